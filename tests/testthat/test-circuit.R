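test_that("sigmoid is the scaled hyperbolic tangent with its symmetries", {
  expect_identical(sigmoid(0), 0.5)
  x <- seq(-8, 8, by = 0.25)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)), tolerance = 1e-15)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_equal(sigmoid(50), 1)
  expect_equal(sigmoid(-50), 0)
  expect_equal(sigmoid(-0.357), (1 + tanh(-0.357)) / 2, tolerance = 1e-15)
})

test_that("resting node activities match term-by-term evaluation", {
  cp <- vehicle_circuit(recenter = FALSE)
  act <- node_activities(t = 150, conc = 0, params = cp)
  s <- function(x) (1 + tanh(x)) / 2
  expect_equal(act$P_Exc, s(-0.357), tolerance = 1e-12)   # ~0.3287
  expect_equal(act$P_Inh, s(-1.335), tolerance = 1e-12)   # ~0.0648
  expect_equal(act$P_HD, s(-3.69), tolerance = 1e-12)     # ~0.0006
  expect_equal(act$P_SPN,
               9.89 * s(-0.357) - 6.38 * s(-1.335) + 5.66 * s(-3.69) - 3.35,
               tolerance = 1e-12)                          # ~ -0.509 degC
  expect_equal(act$P_SPN, -0.509, tolerance = 1e-3)
  # recentring zeroes the resting drive
  act_rc <- node_activities(t = 150, conc = 0, params = vehicle_circuit())
  expect_identical(act_rc$P_SPN, 0)
})

test_that("excitatory node saturates at high drug input without stress", {
  cp <- vehicle_circuit()
  act <- node_activities(t = 150, conc = 1e4, params = cp)
  expect_equal(act$P_Exc, 1, tolerance = 1e-12)
  expect_true(all(act$P_Exc <= 1 & act$P_Inh <= 1 & act$P_HD <= 1))
})

test_that("a zero inhibition cap silences Inhib and leaves Med purely excitatory", {
  cp <- vehicle_circuit(inhib_cap = 0)
  act <- node_activities(t = seq(0, 100, 10), conc = seq(0, 10, 1), params = cp,
                         schedule = injection_schedule(meth_dose = 5))
  expect_true(all(act$P_Inh == 0))
  expect_equal(act$P_Med, cp$w_Exc_Med * act$P_Exc, tolerance = 1e-15)
})

test_that("an inhibition cap of 1 reproduces the uncapped model bit-for-bit", {
  base <- vehicle_circuit()
  capped <- vehicle_circuit(inhib_cap = 1)
  conc <- c(0, 0.3, 1.4, 3.61, 7.2, 10)
  stress <- c(0, 1, 0.5, 0, 0.2, 0)
  a <- node_activities(seq_along(conc), conc, base, stress = stress)
  b <- node_activities(seq_along(conc), conc, capped, stress = stress)
  expect_identical(a, b)
  sched <- injection_schedule(meth_dose = 3)
  ta <- simulate_temperature(sched, base, table1_pk(), table1_thermo(), std_grid())
  tb <- simulate_temperature(sched, capped, table1_pk(), table1_thermo(), std_grid())
  expect_identical(ta$temp_c, tb$temp_c)
})

test_that("medullary drive decreases linearly in inhibitory activity", {
  cp <- vehicle_circuit()
  # raising conc raises P_Inh; at fixed P_Exc (stress compensates), Med falls
  act <- node_activities(0, conc = seq(0, 5, 0.5), params = cp, stress = 0)
  med_from_parts <- cp$w_Exc_Med * act$P_Exc - cp$w_Inh_Med * act$P_Inh
  expect_equal(act$P_Med, med_from_parts, tolerance = 1e-15)
  expect_true(all(diff(cp$w_Exc_Med * act$P_Exc - act$P_Med) >= 0))
})

test_that("activation curves respect the closed-form half-activation points", {
  cp <- vehicle_circuit()
  grid <- seq(0, 10, by = 0.01)
  exc <- activation_curve("Exc", grid, cp)
  expect_true(all(diff(exc$activity) >= 0))
  # Inhib half-activation at -gamma_Inh / w_Inh
  half <- -cp$gamma_Inh / cp$w_Inh
  expect_equal(activation_curve("Inh", half, cp)$activity, 0.5,
               tolerance = 1e-12)
  # reducing w_Inh (antagonist-like) moves the half-activation point upward
  cp_sb <- update_params(cp, w_Inh = 0.5)
  expect_gt(-cp_sb$gamma_Inh / cp_sb$w_Inh, half)
  expect_lt(activation_curve("Inh", half, cp_sb)$activity, 0.5)
  # under the gamma_hd parametrization, a lower basal tone lowers the HD
  # half-activation concentration
  cp_g <- update_params(cp, variant = "gamma_hd")
  cp_g2 <- update_params(cp_g, gamma_HD = -2.5)
  expect_lt(-cp_g2$gamma_HD / cp_g2$w_HD, -cp_g$gamma_HD / cp_g$w_HD)
  h2 <- -cp_g2$gamma_HD / cp_g2$w_HD
  expect_equal(activation_curve("HD", h2, cp_g2)$activity, 0.5,
               tolerance = 1e-12)
  expect_error(activation_curve("Exc", c(-1, 2), cp), "nonnegative")
})

test_that("raising w_HD and lowering gamma_HD give nearly identical activation curves when matched at half-activation", {
  grid <- seq(0, 10, by = 0.02)
  w0 <- 0.8; g0 <- -3.69
  f <- 1.04  # modest sensitization
  via_w <- activation_curve("HD", grid, vehicle_circuit(w_HD = w0 * f))
  via_g <- activation_curve("HD", grid,
                            vehicle_circuit(w_HD = w0, gamma_HD = g0 / f))
  expect_equal(-g0 / (w0 * f), -(g0 / f) / w0, tolerance = 1e-12)
  expect_lt(max(abs(via_w$activity - via_g$activity)), 0.01)
})

test_that("extended variant inhibits HD through the Inhib population", {
  ext <- vehicle_circuit(variant = "extended", w_Inh_HD = 5)
  base <- vehicle_circuit()
  conc <- seq(0, 10, 0.5)
  a_ext <- node_activities(0, conc, ext, stress = 0)
  a_base <- node_activities(0, conc, base, stress = 0)
  expect_true(all(a_ext$P_HD <= a_base$P_HD + 1e-12))
  # HD stays near-silent at 5 mg/kg peak concentration under vehicle weights
  peak5 <- max(meth_concentration(seq(0, 180, 0.5), 5, table1_pk()))
  expect_lt(node_activities(0, peak5, ext, stress = 0)$P_HD, 0.05)
  # silencing Inhib disinhibits HD in the extended circuit
  ext0 <- update_params(ext, inhib_cap = 0)
  expect_gt(node_activities(0, peak5, ext0, stress = 0)$P_HD,
            node_activities(0, peak5, ext, stress = 0)$P_HD)
})

test_that("circuit parameter validation rejects malformed inputs", {
  expect_error(circuit_params(w_Inh = -0.1), ">= 0")
  expect_error(circuit_params(inhib_cap = 1.5), "inhib_cap")
  expect_error(circuit_params(variant = "banana"))
  expect_error(update_params(vehicle_circuit(), nonsense = 1), "unknown")
  expect_error(node_activities(0, -1, vehicle_circuit()), "nonnegative")
})
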