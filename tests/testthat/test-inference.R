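truth_W <- function() scenario_truths()$vehicle

noiseless_series <- function(meth_dose = 5, sd = 1) {
  tr <- simulate_temperature(injection_schedule(meth_dose = meth_dose),
                             vehicle_circuit(), table1_pk(), table1_thermo(),
                             std_grid())
  temperature_series(tr$time_min, tr$temp_c, rep(sd, nrow(tr)), n = 7,
                     meth_dose = meth_dose)
}

test_that("log-posterior is zero at the generating truth on noiseless data", {
  s <- noiseless_series()
  expect_identical(log_posterior(truth_W(), s), 0)
  # and strictly negative away from it
  off <- truth_W(); off["w_Exc"] <- off["w_Exc"] * 1.2
  expect_lt(log_posterior(off, s), 0)
})

test_that("a 1-degree error at one point with unit sigma costs exactly one half", {
  s <- noiseless_series(sd = 1)
  s$mean[60] <- s$mean[60] + 1
  expect_equal(log_posterior(truth_W(), s), -0.5, tolerance = 1e-12)
})

test_that("vectorized likelihood equals the naive loop over the 116-point grid", {
  set.seed(3)
  s <- noiseless_series(sd = 0.3)
  s$mean <- s$mean + rnorm(length(s$mean), 0, 0.3)
  expect_length(s$times, 116)
  theta <- truth_W() * c(1.1, 0.9, 1.05, 1)
  model <- simulate_temperature(
    injection_schedule(meth_dose = 5),
    do.call(update_params, c(list(vehicle_circuit()), as.list(theta))),
    table1_pk(), table1_thermo(), std_grid())$temp_c
  brute <- 0
  for (i in seq_along(s$times))
    brute <- brute - (s$mean[i] - model[i])^2 / (2 * max(s$sd[i], 0.05)^2)
  expect_equal(log_posterior(theta, s), brute, tolerance = 1e-12)
})

test_that("scaling all sigmas by c rescales the log-posterior by 1/c^2", {
  set.seed(4)
  s <- noiseless_series(sd = 0.5)
  s$mean <- s$mean + rnorm(length(s$mean), 0, 0.3)
  lp1 <- log_posterior(truth_W(), s)
  s2 <- s; s2$sd <- 3 * s2$sd
  expect_equal(log_posterior(truth_W(), s2), lp1 / 9, tolerance = 1e-12)
})

test_that("the flat prior support excludes negative sensitivities and time constants", {
  s <- noiseless_series()
  lp <- make_log_posterior(s, sampled = c("w_S", "w_Exc"))
  expect_identical(lp(c(w_S = 1, w_Exc = -0.1)), -Inf)
  expect_true(is.finite(lp(c(w_S = -1, w_Exc = 0.5))))  # w_S unconstrained
  lpt <- make_log_posterior(s, sampled = "tau_T")
  expect_identical(lpt(c(tau_T = -10)), -Inf)
  expect_error(make_log_posterior(s, sampled = "bogus"), "unknown")
})

test_that("joint data from several groups add their likelihood contributions", {
  s1 <- noiseless_series(meth_dose = 1)
  s5 <- noiseless_series(meth_dose = 5)
  s1$mean[10] <- s1$mean[10] + 1
  s5$mean[20] <- s5$mean[20] + 2
  expect_equal(log_posterior(truth_W(), list(s1, s5)),
               log_posterior(truth_W(), s1) + log_posterior(truth_W(), s5),
               tolerance = 1e-12)
})

test_that("the sampler recovers the moments of a known Gaussian", {
  lp <- function(th) -0.5 * (th[["x"]] - 2)^2 / 0.25  # N(2, 0.5^2)
  ens <- mh_sample(lp, c(x = 0),
                   mcmc_settings(n_steps = 30000, burn_in = 5000, thin = 5,
                                 seed = 11))
  n_eff <- nrow(ens$samples)  # thinned; treat as weakly correlated
  expect_lt(abs(ens$mean[["x"]] - 2), 3 * 0.5 / sqrt(n_eff) * 3)
  expect_lt(abs(ens$se[["x"]]^2 / 0.25 - 1), 0.2)
  expect_gt(ens$acceptance_rate, 0.1)
  expect_lt(ens$acceptance_rate, 0.6)
})

test_that("chains are exactly reproducible under a fixed seed and mix across halves", {
  lp <- function(th) -0.5 * sum((th - c(1, -1))^2)
  st <- mcmc_settings(n_steps = 20000, burn_in = 4000, thin = 4, seed = 7)
  e1 <- mh_sample(lp, c(a = 0, b = 0), st)
  e2 <- mh_sample(lp, c(a = 0, b = 0), st)
  expect_identical(e1$samples, e2$samples)
  half <- nrow(e1$samples) %/% 2
  m1 <- colMeans(e1$samples[1:half, ])
  m2 <- colMeans(e1$samples[(half + 1):nrow(e1$samples), ])
  mc_err <- apply(e1$samples, 2, sd) / sqrt(half) * 4
  expect_true(all(abs(m1 - m2) < 4 * mc_err))
})

test_that("single-parameter recovery finds the generating sensitivity", {
  g <- generate_group(truth_W(), design_spec(), iid_noise(seed = 21),
                      sb_dose = 0, meth_dose = 5)
  ens <- mcmc_sample(g$series, sampled = "w_Exc",
                     init = c(w_Exc = 1.3),
                     circuit = vehicle_circuit(),
                     settings = mcmc_settings(6000, 2000, thin = 4, seed = 21))
  expect_lt(abs(ens$mean[["w_Exc"]] - truth_W()[["w_Exc"]]),
            3 * ens$se[["w_Exc"]])
})

test_that("the two-sample z-test matches its closed form and symmetries", {
  fake <- function(m, se) structure(list(mean = c(p = m), se = c(p = se)),
                                    class = "posterior_ensemble")
  same <- compare_groups(fake(1.3, 0.1), fake(1.3, 0.2), "p")
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  r <- compare_groups(fake(1.5, 0.1), fake(1.0, 0.1), "p",
                      labels = c("vehicle", "SB30"))
  expect_equal(r$z, 0.5 / sqrt(0.02), tolerance = 1e-12)  # ~3.536
  expect_equal(r$p_value, 2 * pnorm(-0.5 / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(r$p_value, 4.07e-4, tolerance = 1e-2)
  expect_true(r$significant)

  swapped <- compare_groups(fake(1.0, 0.1), fake(1.5, 0.1), "p")
  expect_equal(swapped$z, -r$z)
  expect_equal(swapped$p_value, r$p_value)

  expect_error(compare_groups(fake(1, 0), fake(1, 0), "p"), "zero combined")
  expect_error(compare_groups(fake(1, 1), fake(1, 1), "q"), "not in ensemble")
})

test_that("temperature series validate their inputs and round-trip to text", {
  expect_error(temperature_series(c(0, 0, 2), 1:3, rep(0.1, 3), 7),
               "increasing")
  expect_error(temperature_series(1:3, 1:3, rep(0.1, 3), 1), "n >= 2")
  expect_error(temperature_series(1:3, 1:2, rep(0.1, 3), 7), "equal length")
  s <- noiseless_series(meth_dose = 10, sd = 0.4)
  path <- tempfile(fileext = ".csv")
  write_temperature_series(s, path)
  back <- read_temperature_series(path)
  expect_equal(back$mean, s$mean, tolerance = 1e-10)
  expect_equal(back$meth_dose, 10)
  expect_equal(back$n, s$n)
})
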