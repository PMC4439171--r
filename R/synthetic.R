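#' Study design specification
#'
#' Describes the structure of the telemetry experiment the generator
#' emulates: two injections (pretreatment at -30 min, treatment at 0 min),
#' core temperature sampled every 2 minutes from -50 to 180 min, groups of
#' 6--8 rats, antagonist pretreatment doses {0, 10, 30} mg/kg crossed with
#' treatment doses {0, 1, 5, 10} mg/kg, baseline near 37 degC.
#'
#' @param sb_doses antagonist pretreatment doses, mg/kg
#' @param meth_doses treatment doses, mg/kg (0 = saline)
#' @param n_per_group animals per group (>= 2)
#' @param step sampling interval, minutes
#' @param window recording window `c(start, end)`, minutes; must cover both
#'   injections
#' @param pretreat_time,meth_time injection times, minutes
#' @return an object of class `design_spec`
#' @export
design_spec <- function(sb_doses = c(0, 10, 30), meth_doses = c(0, 1, 5, 10),
                        n_per_group = 7, step = 2, window = c(-50, 180),
                        pretreat_time = -30, meth_time = 0) {
  if (n_per_group < 2) stop("design_spec: need n_per_group >= 2")
  if (window[1] > pretreat_time || window[2] < meth_time)
    stop("design_spec: recording window must cover both injections")
  structure(list(sb_doses = sb_doses, meth_doses = meth_doses,
                 n_per_group = as.integer(n_per_group), step = step,
                 window = window, pretreat_time = pretreat_time,
                 meth_time = meth_time,
                 times = seq(window[1], window[2], by = step)),
            class = "design_spec")
}

#' Noise specification for synthetic telemetry
#'
#' Per-animal measurement noise: an AR(1) process (telemetric temperature
#' residuals are smooth, so serially correlated noise is the realistic
#' default) plus a constant per-animal baseline offset. The AR(1) innovations
#' have standard deviation `sd`, giving stationary variance
#' `sd^2 / (1 - ar1^2)`; set `ar1 = 0` for iid Gaussian noise exactly
#' matching the fitting likelihood, and all SDs to 0 for noiseless output.
#'
#' @param sd innovation SD per time point, degC
#' @param ar1 AR(1) coefficient in `[0, 1)`
#' @param baseline_sd SD of the per-animal constant baseline offset, degC
#' @param seed RNG seed
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(sd = 0.3, ar1 = 0.5, baseline_sd = 0.2, seed = 42) {
  if (sd < 0 || baseline_sd < 0) stop("noise_spec: SDs must be nonnegative")
  if (ar1 < 0 || ar1 >= 1) stop("noise_spec: ar1 must lie in [0, 1)")
  structure(list(sd = sd, ar1 = ar1, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default drug-sensitive weights for the three pretreatment scenarios
#'
#' The package's reference truth vectors used by the generator and the
#' recovery tests. They are chosen (not fitted) so that the qualitative
#' pharmacology holds: the Exc and Inhib drug sensitivities fall with
#' antagonist dose, the HD sensitivity rises (disinhibition), the stress
#' amplitude falls from vehicle with little difference between the two
#' antagonist doses, and the half-activation concentrations order
#' Exc < Inhib < HD under vehicle.
#'
#' @return named list of named numeric vectors (`vehicle`, `SB10`, `SB30`),
#'   each with entries `w_S`, `w_Exc`, `w_Inh`, `w_HD`
#' @export
scenario_truths <- function() {
  list(vehicle = c(w_S = 2.0, w_Exc = 0.85, w_Inh = 1.0, w_HD = 0.8),
       SB10    = c(w_S = 1.2, w_Exc = 0.55, w_Inh = 0.95, w_HD = 1.1),
       SB30    = c(w_S = 1.0, w_Exc = 0.35, w_Inh = 0.5, w_HD = 1.4))
}

#' Generate one synthetic group
#'
#' Simulates the noiseless model trajectory for the group's schedule, then
#' adds, per animal, a constant baseline offset and AR(1) Gaussian noise, and
#' summarizes the animals into the group mean/SD series consumed by the
#' fitting machinery.
#'
#' With `baseline_correct = TRUE` (default) each animal is re-referenced to
#' its own pre-injection baseline (its mean over the samples before the
#' pretreatment injection), mirroring how telemetry studies analyse changes
#' from baseline; this is what makes group curves comparable to a model whose
#' resting temperature is pinned at `T0`. Set it to `FALSE` to keep raw
#' absolute temperatures (e.g. when studying the noise process itself).
#'
#' @param true_W named numeric of drug-sensitive weights used as the
#'   generating truth (entries among `w_S`, `w_Exc`, `w_Inh`, `w_HD`,
#'   `gamma_HD`), or `NULL` to use `circuit` as is
#' @param design a [design_spec()]
#' @param noise a [noise_spec()]
#' @param sb_dose,meth_dose group labels / treatment dose, mg/kg
#' @param circuit,pk,thermo model parameters (the truth for everything not in
#'   `true_W`)
#' @param seed RNG seed; defaults to `noise$seed`
#' @param baseline_correct re-reference each animal to its pre-injection
#'   baseline (see Details)
#' @return list with elements `series` (a [temperature_series()]), `animals`
#'   (n x time matrix, after any baseline correction), `noiseless` (model
#'   trajectory) and `truth`
#' @export
#' @examples
#' g <- generate_group(scenario_truths()$vehicle, design_spec(),
#'                     noise_spec(seed = 1), sb_dose = 0, meth_dose = 5)
#' g$series
generate_group <- function(true_W = NULL, design = design_spec(),
                           noise = noise_spec(), sb_dose = 0, meth_dose = 0,
                           circuit = circuit_params(), pk = pk_params(),
                           thermo = thermo_params(), seed = noise$seed,
                           baseline_correct = TRUE) {
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_spec"))
  if (!is.null(true_W))
    circuit <- do.call(update_params, c(list(circuit), as.list(true_W)))
  sched <- injection_schedule(meth_dose = meth_dose,
                              meth_time = design$meth_time,
                              pretreat_time = design$pretreat_time,
                              pretreat_label = if (sb_dose > 0)
                                paste0("SB", sb_dose) else "vehicle")
  traj <- simulate_temperature(sched, circuit, pk, thermo,
                               t_grid = design$times,
                               t_start = design$window[1])
  n <- design$n_per_group
  m <- length(design$times)
  set.seed(seed)
  offsets <- stats::rnorm(n, 0, noise$baseline_sd)
  animals <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    if (noise$sd > 0) {
      e <- numeric(m)
      e[1] <- stats::rnorm(1, 0, noise$sd / sqrt(1 - noise$ar1^2))
      if (m > 1) {
        innov <- stats::rnorm(m - 1, 0, noise$sd)
        for (k in 2:m) e[k] <- noise$ar1 * e[k - 1] + innov[k - 1]
      }
    } else e <- numeric(m)
    animals[i, ] <- traj$temp_c + offsets[i] + e
  }
  pre <- design$times < design$pretreat_time
  if (baseline_correct && any(pre)) {
    # shift each animal by its pre-injection deviation from the noiseless
    # baseline (exactly zero when no noise was added)
    ref <- mean(traj$temp_c[pre])
    animals <- animals - (rowMeans(animals[, pre, drop = FALSE]) - ref)
  }
  series <- temperature_series(design$times, colMeans(animals),
                               apply(animals, 2, stats::sd), n,
                               sb_dose = sb_dose, meth_dose = meth_dose,
                               schedule = sched)
  list(series = series, animals = animals, noiseless = traj,
       truth = list(W = true_W, circuit = circuit, pk = pk, thermo = thermo,
                    seed = seed))
}

#' Generate a full synthetic study
#'
#' Emits every pretreatment x treatment combination of the design (12 groups
#' under the default 3 x 4 design), using one truth vector per pretreatment
#' dose, and records the generating truth for recovery testing. Per-group
#' seeds are derived deterministically from `noise$seed`.
#'
#' @param scenario named list mapping pretreatment scenario to truth vector;
#'   names must be `vehicle`, `SB10`, `SB30`, ... matching
#'   `paste0("SB", sb_dose)` (with `vehicle` for dose 0). Defaults to
#'   [scenario_truths()].
#' @param design a [design_spec()]
#' @param noise a [noise_spec()]
#' @param circuit,pk,thermo model parameters shared by all groups
#' @param dir optional directory; when given, each group is written as
#'   delimited text and the truth record as `truth.json`
#' @param baseline_correct passed to [generate_group()]
#' @return list with `groups` (list of per-group results keyed
#'   `"SB<sb>_Meth<meth>"`), `by_sb_dose` (lists of [temperature_series()]
#'   per pretreatment dose, ready for joint fitting) and `truth`
#' @export
generate_study <- function(scenario = scenario_truths(),
                           design = design_spec(), noise = noise_spec(),
                           circuit = circuit_params(), pk = pk_params(),
                           thermo = thermo_params(), dir = NULL,
                           baseline_correct = TRUE) {
  label <- function(sb) if (sb > 0) paste0("SB", sb) else "vehicle"
  missing_sc <- setdiff(vapply(design$sb_doses, label, ""), names(scenario))
  if (length(missing_sc))
    stop("generate_study: scenario missing truth for: ",
         paste(missing_sc, collapse = ", "))
  groups <- list()
  by_sb <- stats::setNames(vector("list", length(design$sb_doses)),
                           vapply(design$sb_doses, label, ""))
  idx <- 0L
  for (sb in design$sb_doses) {
    for (meth in design$meth_doses) {
      idx <- idx + 1L
      g <- generate_group(scenario[[label(sb)]], design, noise,
                          sb_dose = sb, meth_dose = meth,
                          circuit = circuit, pk = pk, thermo = thermo,
                          seed = noise$seed + idx,
                          baseline_correct = baseline_correct)
      key <- sprintf("SB%g_Meth%g", sb, meth)
      groups[[key]] <- g
      by_sb[[label(sb)]] <- c(by_sb[[label(sb)]], list(g$series))
    }
  }
  truth <- list(scenario = lapply(scenario, as.list),
                noise = unclass(noise),
                design = unclass(design)[c("sb_doses", "meth_doses",
                                           "n_per_group", "step", "window")],
                root_seed = noise$seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (key in names(groups))
      write_temperature_series(groups[[key]]$series,
                               file.path(dir, paste0(key, ".csv")))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(groups = groups, by_sb_dose = by_sb, truth = truth)
}
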