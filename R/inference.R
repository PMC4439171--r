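#' Group temperature series
#'
#' Container for one experimental group's telemetry summary: times (minutes
#' relative to the treatment injection), group mean and standard deviation of
#' body temperature, and group size. Carries its injection schedule so the
#' model knows the dose and the stress events.
#'
#' @param times sampling times, minutes (strictly increasing)
#' @param mean group mean temperature, degC
#' @param sd group standard deviation, degC (nonnegative; floored downstream)
#' @param n number of animals (>= 2)
#' @param sb_dose antagonist pretreatment dose label, mg/kg
#' @param meth_dose treatment dose, mg/kg
#' @param schedule optional [injection_schedule()]; defaults to the standard
#'   protocol (pretreatment at -30 min, treatment at 0 min)
#' @return an object of class `temperature_series`
#' @export
temperature_series <- function(times, mean, sd, n, sb_dose = 0, meth_dose = 0,
                               schedule = NULL) {
  if (any(diff(times) <= 0))
    stop("temperature_series: times must be strictly increasing")
  if (length(mean) != length(times) || length(sd) != length(times))
    stop("temperature_series: times, mean and sd must have equal length")
  if (any(sd < 0)) stop("temperature_series: sd must be nonnegative")
  if (n < 2) stop("temperature_series: need n >= 2 animals")
  if (is.null(schedule)) schedule <- injection_schedule(meth_dose = meth_dose)
  structure(list(times = as.numeric(times), mean = as.numeric(mean),
                 sd = as.numeric(sd), n = as.integer(n),
                 sb_dose = sb_dose, meth_dose = meth_dose,
                 schedule = schedule),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Temperature series: SB %s mg/kg, Meth %s mg/kg, n = %d, %d points [%g, %g] min\n",
              format(x$sb_dose), format(x$meth_dose), x$n, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(time_min = x$times, mean_c = x$mean, sd_c = x$sd, n = x$n)
}

#' Write / read a group temperature series as delimited text
#'
#' CSV with columns `time_min, mean_c, sd_c, n`; group labels are kept in
#' `# sb_dose:` / `# meth_dose:` header comment lines.
#'
#' @param series a [temperature_series()]
#' @param path file path
#' @return `read_temperature_series` returns a `temperature_series`;
#'   the writer returns `path` invisibly
#' @export
write_temperature_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sb_dose: %s", format(series$sb_dose)),
               sprintf("# meth_dose: %s", format(series$meth_dose))), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperature_series
#' @export
read_temperature_series <- function(path) {
  hdr <- readLines(path, n = 10)
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1])) else 0
  }
  df <- utils::read.csv(path, comment.char = "#")
  temperature_series(df$time_min, df$mean_c, df$sd_c, df$n[1],
                     sb_dose = get_num("sb_dose"),
                     meth_dose = get_num("meth_dose"))
}

# parameter routing tables -------------------------------------------------

.circuit_par_names <- c("w_S", "w_Exc", "w_Inh", "w_HD",
                        "gamma_Exc", "gamma_Inh", "gamma_HD", "w_Inh_HD")
.pk_par_names <- c("tau_u", "tau_d", "tau_s")
.thermo_par_names <- c("tau_T", "T0")
.positive_pars <- c("w_Exc", "w_Inh", "w_HD", "tau_u", "tau_d", "tau_s", "tau_T")

#' Build the unnormalized log-posterior over a set of sampled parameters
#'
#' Returns a closure evaluating the log of the posterior density
#' \deqn{\log p(\theta \mid \{T_i\}) = -\sum_{g}\sum_i
#'   \frac{[T_{g,i} - T_\theta(g, i)]^2}{2\sigma_{g,i}^2}}
#' where the sum runs over every supplied group (all groups sharing one
#' antagonist dose are fit jointly) and over their time points. The prior is
#' improper flat on the support: drug sensitivities and time constants must
#' be positive, stress amplitude and basal excitabilities are unconstrained.
#' Group standard deviations are floored at `sd_floor` (default 0.05 degC)
#' to avoid singular weights.
#'
#' The returned function takes a named numeric vector whose names must be a
#' subset of the circuit weights (`w_S`, `w_Exc`, `w_Inh`, `w_HD`,
#' `gamma_HD`, ...), pharmacokinetic constants (`tau_u`, `tau_d`, `tau_s`)
#' and temperature constants (`tau_T`, `T0`); all other parameters stay fixed
#' at the values supplied here. Quantities not touched by the sampled
#' parameters (drug concentration, stress input) are precomputed once, so an
#' evaluation costs a few vectorized operations per group.
#'
#' @param data a [temperature_series()] or list of them (jointly fit)
#' @param sampled character vector naming the sampled parameters
#' @param circuit,pk,thermo fixed model parameters
#' @param sd_floor minimal group SD, degC
#' @param dt integration step, minutes
#' @param t_start integration start, minutes
#' @return function mapping a named numeric vector to a log-density (<= 0;
#'   `-Inf` outside the support)
#' @export
make_log_posterior <- function(data, sampled, circuit = circuit_params(),
                               pk = pk_params(), thermo = thermo_params(),
                               sd_floor = 0.05, dt = 0.1, t_start = -50) {
  if (inherits(data, "temperature_series")) data <- list(data)
  stopifnot(length(data) >= 1,
            all(vapply(data, inherits, TRUE, "temperature_series")))
  known <- c(.circuit_par_names, .pk_par_names, .thermo_par_names)
  bad <- setdiff(sampled, known)
  if (length(bad))
    stop("make_log_posterior: unknown parameter(s): ", paste(bad, collapse = ", "))

  pk_varies <- any(c("tau_u", "tau_d") %in% sampled)
  stress_varies <- "tau_s" %in% sampled

  groups <- lapply(data, function(g) {
    t_start_g <- min(t_start, g$times[1])
    segs <- plan_segments(t_start_g, max(g$times), dt,
                          schedule_events(g$schedule))
    t_eval <- lapply(segs, `[[`, "t_eval")
    t_full <- c(segs[[1]]$t_full,
                unlist(lapply(segs[-1], function(s) s$t_full[-1])))
    list(g = g, segs = segs, t_eval = t_eval, t_full = t_full,
         conc = if (!pk_varies)
           lapply(t_eval, function(tt)
             meth_concentration(tt - g$schedule$meth_time,
                                g$schedule$meth_dose, pk)),
         stress = if (!stress_varies)
           lapply(t_eval, function(tt) total_stress(tt, g$schedule, pk)),
         w = 1 / (2 * pmax(g$sd, sd_floor)^2))
  })

  cp0 <- unclass(circuit)
  pk0 <- unclass(pk)
  th0 <- unclass(thermo)

  function(theta) {
    if (is.null(names(theta))) names(theta) <- sampled
    pos <- intersect(names(theta), .positive_pars)
    if (any(!is.finite(theta)) || any(theta[pos] <= 0)) return(-Inf)
    cp <- cp0; pk1 <- pk0; th <- th0
    for (nm in names(theta)) {
      if (nm %in% .pk_par_names) pk1[[nm]] <- theta[[nm]]
      else if (nm %in% .thermo_par_names) th[[nm]] <- theta[[nm]]
      else cp[[nm]] <- theta[[nm]]
    }
    lp <- 0
    for (gr in groups) {
      conc <- if (pk_varies)
        lapply(gr$t_eval, function(tt)
          meth_concentration_list(tt - gr$g$schedule$meth_time,
                                  gr$g$schedule$meth_dose, pk1))
      else gr$conc
      stress <- if (stress_varies)
        lapply(gr$t_eval, function(tt) {
          s <- numeric(length(tt))
          for (t0 in gr$g$schedule$stress_times)
            s <- s + stress_input(tt, t0, pk1$tau_s)
          s
        })
      else gr$stress
      p <- lapply(seq_along(gr$segs), function(i)
        circuit_activities(conc[[i]], stress[[i]], cp)$P_SPN)
      sol <- propagate_segments(p, gr$segs, th$tau_T)
      model <- th$T0 + stats::approx(gr$t_full, sol$y, xout = gr$g$times)$y
      lp <- lp - sum(gr$w * (gr$g$mean - model)^2)
      if (!is.finite(lp)) return(-Inf)
    }
    lp
  }
}

# meth_concentration for a plain pk list (no class check), used on the hot
# path when pharmacokinetic constants are being sampled.
meth_concentration_list <- function(t, dose, pk) {
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    if (abs(pk$tau_u - pk$tau_d) < 1e-6 * pk$tau_u) {
      out[pos] <- dose * (tp / pk$tau_u) * exp(-tp / pk$tau_u)
    } else {
      out[pos] <- dose / (pk$tau_u / pk$tau_d - 1) *
        (exp(-tp / pk$tau_u) - exp(-tp / pk$tau_d))
    }
  }
  out
}

#' Evaluate the log-posterior at one parameter vector
#'
#' Convenience wrapper around [make_log_posterior()]; see there for the
#' likelihood and prior.
#'
#' @param theta named numeric vector of parameter values
#' @param data a [temperature_series()] or list of them
#' @param circuit,pk,thermo fixed model parameters
#' @param ... passed to [make_log_posterior()]
#' @return log-density (unnormalized, <= 0)
#' @export
log_posterior <- function(theta, data, circuit = circuit_params(),
                          pk = pk_params(), thermo = thermo_params(), ...) {
  f <- make_log_posterior(data, sampled = names(theta), circuit = circuit,
                          pk = pk, thermo = thermo, ...)
  f(theta)
}

#' MCMC sampler settings
#'
#' @param n_steps total chain length
#' @param burn_in steps discarded (proposal scales adapt only here)
#' @param thin keep every `thin`-th post-burn-in state
#' @param seed RNG seed (chains are exactly reproducible under a fixed seed)
#' @param scales initial per-parameter proposal SDs (named, optional)
#' @param adapt adapt proposal scales during burn-in toward 25--40%
#'   acceptance (frozen afterwards, preserving detailed balance)
#' @return a list of class `mcmc_settings`
#' @export
mcmc_settings <- function(n_steps = 50000, burn_in = 10000, thin = 10,
                          seed = 42, scales = NULL, adapt = TRUE) {
  stopifnot(n_steps > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 scales = scales, adapt = isTRUE(adapt)),
            class = "mcmc_settings")
}

#' Random-walk Metropolis--Hastings sampler
#'
#' Samples an arbitrary log-density with symmetric Gaussian proposals and
#' acceptance probability `min(1, exp(delta log-density))`. Proposal scales
#' are adapted in blocks of 100 steps during burn-in toward an acceptance
#' rate of about 0.3 and frozen afterwards. Warns when the post-burn-in
#' acceptance rate falls outside `[0.1, 0.6]`.
#'
#' @param log_post function from a named numeric vector to a log-density
#' @param init named numeric starting point (finite log-density required)
#' @param settings an [mcmc_settings()] object
#' @return an object of class `posterior_ensemble`: post-burn-in thinned
#'   `samples` matrix, their `log_post` values, `acceptance_rate`, frozen
#'   `scales`, the `seed`, and per-parameter `mean` and `se` (the posterior
#'   standard deviation, i.e. the standard error of the ensemble estimate)
#' @export
#' @examples
#' lp <- function(th) -0.5 * (th[["x"]] - 2)^2 / 0.25  # N(2, 0.5^2)
#' ens <- mh_sample(lp, c(x = 0),
#'                  mcmc_settings(n_steps = 4000, burn_in = 1000, seed = 1))
#' ens$mean
mh_sample <- function(log_post, init, settings = mcmc_settings()) {
  stopifnot(inherits(settings, "mcmc_settings"),
            is.numeric(init), !is.null(names(init)))
  d <- length(init)
  scales <- settings$scales
  if (is.null(scales)) scales <- pmax(0.1 * abs(init), 0.01)
  scales <- rep_len(as.numeric(scales), d)

  set.seed(settings$seed)
  cur <- init
  lp_cur <- log_post(cur)
  if (!is.finite(lp_cur))
    stop("mh_sample: initial point has non-finite log-density")

  n_keep <- (settings$n_steps - settings$burn_in) %/% settings$thin
  samples <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, names(init)))
  lps <- numeric(n_keep)
  kept <- 0L
  acc_post <- 0L
  acc_block <- 0L
  block <- 100L

  for (i in seq_len(settings$n_steps)) {
    prop <- cur + stats::rnorm(d, 0, scales)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop; lp_cur <- lp_prop
      acc_block <- acc_block + 1L
      if (i > settings$burn_in) acc_post <- acc_post + 1L
    }
    if (settings$adapt && i <= settings$burn_in && i %% block == 0L) {
      rate <- acc_block / block
      scales <- scales * exp(pmin(pmax(rate - 0.3, -0.7), 0.7))
      acc_block <- 0L
    }
    if (i %% block == 0L && i > settings$burn_in) acc_block <- 0L
    if (i > settings$burn_in &&
        (i - settings$burn_in) %% settings$thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- cur
      lps[kept] <- lp_cur
    }
  }
  acc_rate <- acc_post / (settings$n_steps - settings$burn_in)
  if (acc_rate < 0.1 || acc_rate > 0.6)
    warning(sprintf("mh_sample: acceptance rate %.2f outside [0.1, 0.6]",
                    acc_rate))
  structure(list(samples = samples[seq_len(kept), , drop = FALSE],
                 log_post = lps[seq_len(kept)],
                 acceptance_rate = acc_rate,
                 scales = scales,
                 seed = settings$seed,
                 settings = settings,
                 mean = colMeans(samples[seq_len(kept), , drop = FALSE]),
                 se = apply(samples[seq_len(kept), , drop = FALSE], 2,
                            stats::sd)),
            class = "posterior_ensemble")
}

#' Sample the posterior of model parameters given group temperature data
#'
#' Builds the posterior with [make_log_posterior()] and samples it with
#' [mh_sample()]. All groups in `data` contribute jointly (the per-antagonist
#' dose fits pool the four treatment groups of that dose).
#'
#' @param data a [temperature_series()] or list of them
#' @param sampled names of the sampled parameters (e.g.
#'   `c("w_S", "w_Exc", "w_Inh", "w_HD")`)
#' @param init named starting values; defaults to the values in the fixed
#'   parameter objects
#' @param circuit,pk,thermo fixed model parameters
#' @param settings an [mcmc_settings()] object
#' @param ... passed to [make_log_posterior()] (e.g. `sd_floor`, `dt`)
#' @return a `posterior_ensemble` (see [mh_sample()])
#' @export
mcmc_sample <- function(data, sampled, init = NULL,
                        circuit = circuit_params(), pk = pk_params(),
                        thermo = thermo_params(),
                        settings = mcmc_settings(), ...) {
  lp <- make_log_posterior(data, sampled = sampled, circuit = circuit,
                           pk = pk, thermo = thermo, ...)
  if (is.null(init)) {
    all_fixed <- c(unclass(circuit), unclass(pk), unclass(thermo))
    init <- vapply(sampled, function(nm) as.numeric(all_fixed[[nm]]), 0)
    names(init) <- sampled
  }
  mh_sample(lp, init, settings)
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("Posterior ensemble: %d samples, acceptance rate %.2f (seed %d)\n",
              nrow(x$samples), x$acceptance_rate, x$seed))
  print(data.frame(mean = x$mean, se = x$se))
  invisible(x)
}

#' Posterior summary table
#'
#' @param ensemble a `posterior_ensemble`
#' @return data.frame with columns `parameter`, `mean`, `se`
#' @export
ensemble_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "posterior_ensemble"))
  data.frame(parameter = names(ensemble$mean),
             mean = as.numeric(ensemble$mean),
             se = as.numeric(ensemble$se), row.names = NULL)
}

#' Two-sample z-test between posterior ensembles
#'
#' Compares one parameter's ensemble mean between two fits:
#' `z = (m1 - m2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value;
#' the difference is flagged significant at p < 0.05.
#'
#' @param e1,e2 `posterior_ensemble` objects exposing the parameter
#' @param parameter parameter name
#' @param labels optional length-2 character labels of the two groups
#' @return one-row data.frame with columns `parameter`, `group1`, `group2`,
#'   `z`, `p_value`, `significant`
#' @export
#' @examples
#' lp <- function(th) -0.5 * (th[["x"]])^2
#' e1 <- mh_sample(lp, c(x = 0), mcmc_settings(2000, 500, seed = 1))
#' e2 <- mh_sample(lp, c(x = 0), mcmc_settings(2000, 500, seed = 2))
#' compare_groups(e1, e2, "x")
compare_groups <- function(e1, e2, parameter, labels = c("group1", "group2")) {
  stopifnot(inherits(e1, "posterior_ensemble"),
            inherits(e2, "posterior_ensemble"))
  for (e in list(e1, e2))
    if (!parameter %in% names(e$mean))
      stop("compare_groups: parameter '", parameter, "' not in ensemble")
  se <- sqrt(e1$se[[parameter]]^2 + e2$se[[parameter]]^2)
  if (se == 0) stop("compare_groups: zero combined standard error")
  z <- (e1$mean[[parameter]] - e2$mean[[parameter]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(parameter = parameter, group1 = labels[1], group2 = labels[2],
             z = z, p_value = p, significant = p < 0.05)
}
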