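#' Sigmoid activation function
#'
#' `sigmoid(x) = (1 + tanh(x)) / 2`: monotone increasing from 0 to 1 with
#' `sigmoid(0) = 0.5` and the odd symmetry `sigmoid(x) + sigmoid(-x) = 1`.
#'
#' @param x numeric vector
#' @return activity in `[0, 1]`
#' @export
sigmoid <- function(x) (1 + tanh(x)) / 2

# Resting drive of the premotor output: zero drug, zero stress, intact
# inhibition (cap = 1). Used as the recentring constant so that the resting
# temperature equals T0.
resting_drive <- function(params) {
  p_inh <- sigmoid(params$gamma_Inh)
  hd_arg <- params$gamma_HD
  if (params$variant == "extended") hd_arg <- hd_arg - params$w_Inh_HD * p_inh
  p_exc <- sigmoid(params$gamma_Exc)
  p_hd <- sigmoid(hd_arg)
  params$w_Exc_Med * p_exc - params$w_Inh_Med * p_inh +
    params$w_HD_SPN * p_hd + params$gamma_SPN
}

#' Node activities of the thermoregulatory circuit
#'
#' Instantaneous activities of the drug-sensitive populations (Exc, Inhib,
#' HD), the medullary relay and the sympathetic premotor output, given the
#' blood drug concentration and the stress input:
#' \deqn{P_{Exc} = \sigma(w_S S + w_{Exc}[M] + \gamma_{Exc})}
#' \deqn{P_{Inh} = \min(cap,\ \sigma(w_{Inh}[M] + \gamma_{Inh}))}
#' \deqn{P_{HD} = \sigma(w_{HD}[M] + \gamma_{HD} [- w_{Inh\to HD} P_{Inh}])}
#' \deqn{P_{Med} = w_{Exc\to Med} P_{Exc} - w_{Inh\to Med} P_{Inh}}
#' \deqn{P_{SPN} = P_{Med} + w_{HD\to SPN} P_{HD} + \gamma_{SPN}}
#' The bracketed inhibitory term enters only under the `extended` variant.
#' When a `schedule` is supplied the stress input is the sum of the
#' exponential stress transients of its injections, each carrying the same
#' amplitude `w_S`; alternatively pass the summed unscaled stress directly
#' via `stress`.
#'
#' With `params$recenter = TRUE` the resting drive (zero drug, zero stress,
#' intact inhibition) is subtracted from `P_SPN`, so the premotor output is
#' the drive *relative to baseline* in degrees Celsius.
#'
#' @param t time, minutes (vectorized; only used for the stress transients)
#' @param conc blood drug concentration, mg/kg (scalar or same length as `t`)
#' @param params a [circuit_params()] object
#' @param schedule optional [injection_schedule()] supplying stress events
#' @param pk a [pk_params()] object (stress decay constant); only used with
#'   `schedule`
#' @param stress summed unscaled stress input (overridden by `schedule`)
#' @return data.frame with columns `t`, `P_Exc`, `P_Inh`, `P_HD`
#'   (dimensionless, in `[0, 1]`) and `P_Med`, `P_SPN` (degC)
#' @export
#' @examples
#' cp <- circuit_params()
#' node_activities(t = 150, conc = 0, params = cp)  # resting state
node_activities <- function(t, conc, params, schedule = NULL,
                            pk = pk_params(), stress = 0) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(conc < 0)) stop("node_activities: concentration must be nonnegative")
  if (!is.null(schedule)) stress <- total_stress(t, schedule, pk)
  n <- max(length(t), length(conc), length(stress))
  t <- rep_len(t, n); conc <- rep_len(conc, n); stress <- rep_len(stress, n)
  act <- circuit_activities(conc, stress, params)
  data.frame(t = t, P_Exc = act$P_Exc, P_Inh = act$P_Inh, P_HD = act$P_HD,
             P_Med = act$P_Med, P_SPN = act$P_SPN)
}

# Lean vectorized core shared by node_activities and the likelihood path
# (no validation, no data.frame construction). `params` may be a plain list
# with circuit_params fields.
circuit_activities <- function(conc, stress, params) {
  p_exc <- sigmoid(params$w_S * stress + params$w_Exc * conc + params$gamma_Exc)
  p_inh <- pmin(params$inhib_cap, sigmoid(params$w_Inh * conc + params$gamma_Inh))
  hd_arg <- params$w_HD * conc + params$gamma_HD
  if (params$variant == "extended") hd_arg <- hd_arg - params$w_Inh_HD * p_inh
  p_hd <- sigmoid(hd_arg)
  p_med <- params$w_Exc_Med * p_exc - params$w_Inh_Med * p_inh
  p_spn <- p_med + params$w_HD_SPN * p_hd + params$gamma_SPN
  if (isTRUE(params$recenter)) p_spn <- p_spn - resting_drive(params)
  list(P_Exc = p_exc, P_Inh = p_inh, P_HD = p_hd, P_Med = p_med, P_SPN = p_spn)
}

#' Activation curve of a circuit node over drug concentration
#'
#' Tabulates steady node activity as a function of blood drug concentration
#' with the stress input set to zero; the dose-dependence diagnostic used to
#' compare parameter sets fitted under different antagonist doses. For the
#' sigmoidal nodes the half-activation concentration is the point where the
#' sigmoid argument vanishes, e.g. `-gamma_Inh / w_Inh` for Inhib.
#'
#' @param node one of `"Exc"`, `"Inh"`, `"HD"`, `"Med"`, `"SPN"`
#' @param conc_grid nonnegative concentrations, mg/kg
#' @param params a [circuit_params()] object
#' @return data.frame with columns `conc` and `activity`
#' @export
activation_curve <- function(node = c("Exc", "Inh", "HD", "Med", "SPN"),
                             conc_grid, params) {
  node <- match.arg(node)
  if (any(conc_grid < 0))
    stop("activation_curve: concentrations must be nonnegative")
  act <- node_activities(t = rep(0, length(conc_grid)), conc = conc_grid,
                         params = params, stress = 0)
  col <- switch(node, Exc = "P_Exc", Inh = "P_Inh", HD = "P_HD",
                Med = "P_Med", SPN = "P_SPN")
  data.frame(conc = conc_grid, activity = act[[col]])
}
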