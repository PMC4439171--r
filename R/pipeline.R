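#' Fit the drug-sensitive weights per pretreatment dose and compare them
#'
#' The central analysis: for each antagonist pretreatment dose, all of its
#' treatment groups are fit jointly by MCMC over the drug-sensitive
#' parameter vector -- `(w_S, w_Exc, w_Inh, w_HD)` under the `base` circuit,
#' or `(w_S, w_Exc, w_Inh, gamma_HD)` under the `gamma_hd` variant -- and the
#' resulting posterior ensembles are compared pairwise per parameter with
#' two-sample z-tests.
#'
#' @param data_by_sb named list (one element per pretreatment dose, e.g.
#'   `vehicle`, `SB10`, `SB30`) of lists of [temperature_series()]; the
#'   `by_sb_dose` element of [generate_study()] has this shape
#' @param circuit,pk,thermo fixed model parameters; `circuit$variant`
#'   selects which parameter set is sampled
#' @param settings an [mcmc_settings()]; each pretreatment dose uses
#'   `settings$seed + position - 1` so fits are independent but reproducible
#' @param init optional named starting values for the sampled parameters
#' @param ... passed to [make_log_posterior()]
#' @return list of class `fit_result` with `ensembles` (per dose),
#'   `summary` (parameter means and standard errors per dose) and `ztests`
#'   (one row per parameter and dose pair; 4 x 3 = 12 rows for three doses)
#' @export
#' @examples
#' \donttest{
#' study <- generate_study(noise = noise_spec(ar1 = 0, baseline_sd = 0, seed = 7))
#' fit <- run_fit(study$by_sb_dose,
#'                settings = mcmc_settings(4000, 1000, seed = 7))
#' subset(fit$ztests, significant)
#' }
run_fit <- function(data_by_sb, circuit = circuit_params(), pk = pk_params(),
                    thermo = thermo_params(), settings = mcmc_settings(),
                    init = NULL, ...) {
  stopifnot(is.list(data_by_sb), length(data_by_sb) >= 2,
            !is.null(names(data_by_sb)))
  sampled <- c("w_S", "w_Exc", "w_Inh",
               if (circuit$variant == "gamma_hd") "gamma_HD" else "w_HD")
  ensembles <- list()
  for (i in seq_along(data_by_sb)) {
    dose_settings <- settings
    dose_settings$seed <- settings$seed + i - 1L
    ensembles[[names(data_by_sb)[i]]] <-
      mcmc_sample(data_by_sb[[i]], sampled = sampled, init = init,
                  circuit = circuit, pk = pk, thermo = thermo,
                  settings = dose_settings, ...)
  }
  summ <- do.call(rbind, lapply(names(ensembles), function(nm) {
    cbind(group = nm, ensemble_summary(ensembles[[nm]]))
  }))
  pairs <- utils::combn(names(ensembles), 2, simplify = FALSE)
  ztests <- do.call(rbind, lapply(sampled, function(par) {
    do.call(rbind, lapply(pairs, function(pr) {
      compare_groups(ensembles[[pr[1]]], ensembles[[pr[2]]], par, labels = pr)
    }))
  }))
  rownames(ztests) <- NULL
  structure(list(ensembles = ensembles, summary = summ, ztests = ztests,
                 sampled = sampled),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit over", length(x$ensembles), "pretreatment groups\n\n")
  print(x$summary, row.names = FALSE)
  cat("\nPairwise z-tests:\n")
  print(x$ztests, row.names = FALSE)
  invisible(x)
}

#' Inhibition-failure scenario specification
#'
#' Settings of the simulation probing hyperthermia risk when the inhibitory
#' population loses capacity: a treatment dose (a low dose that produces no
#' major response with intact inhibition) and a descending list of caps on
#' the maximal Inhib activity (1 = intact, 0.5 = half capacity, 0 =
#' silenced).
#'
#' @param meth_dose treatment dose, mg/kg
#' @param fractions inhibition fractions, sorted descending from 1.0
#' @param variant circuit variant to simulate under
#' @param t_grid output time grid, minutes
#' @return an object of class `scenario_spec`
#' @export
scenario_spec <- function(meth_dose = 3, fractions = c(1, 0.5, 0),
                          variant = c("extended", "base", "gamma_hd"),
                          t_grid = seq(-50, 180, by = 2)) {
  variant <- match.arg(variant)
  if (any(fractions < 0 | fractions > 1))
    stop("scenario_spec: fractions must lie in [0, 1]")
  if (is.unsorted(rev(fractions), strictly = TRUE) || fractions[1] != 1)
    stop("scenario_spec: fractions must be sorted descending from 1.0")
  structure(list(meth_dose = meth_dose, fractions = fractions,
                 variant = variant, t_grid = t_grid),
            class = "scenario_spec")
}

#' Simulate temperature responses under failing inhibition
#'
#' Runs the model once per inhibition fraction, capping the maximal Inhib
#' activity at that fraction (a hard ceiling, not a rescaling), and
#' summarizes peak temperatures. Peak temperature is monotonically
#' non-increasing in the fraction: the weaker the inhibition, the hotter the
#' response to the same dose.
#'
#' @param scenario a [scenario_spec()]
#' @param circuit,pk,thermo model parameters (vehicle-like weights by
#'   default); `circuit$variant` is overridden by the scenario's
#' @return list of class `failure_result` with `trajectories` (one
#'   `temperature_trajectory` per fraction, named `"cap_<fraction>"`) and
#'   `peaks` (data.frame `fraction`, `peak_temp_c`, `peak_time_min`)
#' @export
#' @examples
#' res <- run_inhibition_failure(scenario_spec())
#' res$peaks
run_inhibition_failure <- function(scenario = scenario_spec(),
                                   circuit = circuit_params(),
                                   pk = pk_params(),
                                   thermo = thermo_params()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  sched <- injection_schedule(meth_dose = scenario$meth_dose)
  trajectories <- list()
  peaks <- data.frame(fraction = scenario$fractions, peak_temp_c = NA_real_,
                      peak_time_min = NA_real_)
  for (i in seq_along(scenario$fractions)) {
    f <- scenario$fractions[i]
    cp <- update_params(circuit, inhib_cap = f, variant = scenario$variant)
    tr <- simulate_temperature(sched, cp, pk, thermo, t_grid = scenario$t_grid)
    trajectories[[paste0("cap_", f)]] <- tr
    peaks$peak_temp_c[i] <- max(tr$temp_c)
    peaks$peak_time_min[i] <- tr$time_min[which.max(tr$temp_c)]
  }
  structure(list(trajectories = trajectories, peaks = peaks,
                 scenario = scenario),
            class = "failure_result")
}

#' Node activation curves and drug time courses per parameter set
#'
#' Tabulates the activity of every circuit node over a blood-concentration
#' grid for each supplied parameter set (typically the fitted vehicle /
#' antagonist parametrizations), together with the simulated concentration
#' time courses of the treatment doses. Concentration curves are linear in
#' dose, so the time of peak is dose-independent and peak heights scale with
#' the dose ratio.
#'
#' @param param_sets named list of [circuit_params()] objects, or of named
#'   weight vectors applied on top of `circuit`
#' @param circuit base circuit for weight-vector entries
#' @param pk a [pk_params()] object
#' @param conc_grid concentration grid, mg/kg
#' @param doses treatment doses for the time courses, mg/kg
#' @param t_grid time grid for the time courses, minutes
#' @return list with `curves` (data.frame `set`, `node`, `conc`, `activity`)
#'   and `concentration` (data.frame `dose`, `time_min`, `conc`)
#' @export
run_activation_curves <- function(param_sets = scenario_truths(),
                                  circuit = circuit_params(),
                                  pk = pk_params(),
                                  conc_grid = seq(0, 10, by = 0.05),
                                  doses = c(1, 5, 10),
                                  t_grid = seq(0, 180, by = 1)) {
  nodes <- c("Exc", "Inh", "HD", "SPN")
  curves <- do.call(rbind, lapply(names(param_sets), function(nm) {
    ps <- param_sets[[nm]]
    if (!inherits(ps, "circuit_params"))
      ps <- do.call(update_params, c(list(circuit), as.list(ps)))
    do.call(rbind, lapply(nodes, function(nd) {
      cv <- activation_curve(nd, conc_grid, ps)
      data.frame(set = nm, node = nd, conc = cv$conc, activity = cv$activity)
    }))
  }))
  concentration <- do.call(rbind, lapply(doses, function(d) {
    data.frame(dose = d, time_min = t_grid,
               conc = meth_concentration(t_grid, d, pk))
  }))
  list(curves = curves, concentration = concentration)
}

#' Load an analysis configuration
#'
#' Reads a YAML configuration and merges it over the package defaults. The
#' recognized sections mirror the model components: `pk` (`tau_u`, `tau_d`,
#' `tau_s`), `thermo` (`tau_T`, `T0`), `circuit` (all weights, `variant`,
#' `inhib_cap`, `raw_gamma_spn` to disable baseline recentring), `design`,
#' `noise` and `mcmc`. With `path = NULL` the defaults are returned.
#'
#' @param path YAML file path, or `NULL`
#' @return nested list of configuration values
#' @seealso [config_params()] to turn a configuration into parameter objects
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    pk = list(tau_u = 8.25, tau_d = 57.5, tau_s = 10),
    thermo = list(tau_T = 89.2, T0 = 37),
    circuit = c(as.list(scenario_truths()$vehicle),
                list(gamma_Exc = -0.357, gamma_Inh = -1.335,
                     gamma_HD = -3.69, w_Exc_Med = 9.89, w_Inh_Med = 6.38,
                     w_HD_SPN = 5.66, gamma_SPN = -3.35, variant = "base",
                     w_Inh_HD = 5.0, inhib_cap = 1.0,
                     raw_gamma_spn = FALSE)),
    design = list(sb_doses = c(0, 10, 30), meth_doses = c(0, 1, 5, 10),
                  n_per_group = 7, step = 2, window = c(-50, 180)),
    noise = list(sd = 0.3, ar1 = 0.5, baseline_sd = 0.2, seed = 42),
    mcmc = list(n_steps = 50000, burn_in = 10000, thin = 10, seed = 42))
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

#' Build parameter objects from a configuration
#'
#' @param config a configuration list from [load_config()]
#' @return list with elements `circuit`, `pk`, `thermo`, `design`, `noise`,
#'   `mcmc`
#' @export
config_params <- function(config = load_config()) {
  cc <- config$circuit
  recenter <- !isTRUE(cc$raw_gamma_spn)
  cc$raw_gamma_spn <- NULL
  list(circuit = do.call(circuit_params, c(cc, list(recenter = recenter))),
       pk = do.call(pk_params, config$pk),
       thermo = do.call(thermo_params, config$thermo),
       design = do.call(design_spec, config$design),
       noise = do.call(noise_spec, config$noise),
       mcmc = do.call(mcmc_settings, config$mcmc))
}

#' @export
plot.temperature_trajectory <- function(x, ..., col = "firebrick", lwd = 2) {
  graphics::plot(x$time_min, x$temp_c, type = "l", col = col, lwd = lwd,
                 xlab = "time (min)", ylab = "body temperature (°C)", ...)
  invisible(x)
}
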