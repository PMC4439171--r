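#' Pharmacokinetic parameters
#'
#' Time constants of the absorption--elimination model of intraperitoneal
#' methamphetamine and of the injection-stress input. Defaults are the fixed
#' constants used throughout: absorption 8.25 min, elimination 57.5 min,
#' stress decay 10 min.
#'
#' `tau_u` is interpreted as the absorption time constant (peritoneum to
#' blood) and `tau_d` as the elimination time constant. The closed-form
#' blood-concentration curve is singular at `tau_u == tau_d`, so exact
#' equality is rejected; near-equal values are handled by a limiting form
#' (see [meth_concentration()]).
#'
#' @param tau_u absorption time constant, minutes (> 0)
#' @param tau_d elimination time constant, minutes (> 0, != `tau_u`)
#' @param tau_s stress-input decay time constant, minutes (> 0)
#' @return an object of class `pk_params`
#' @export
#' @examples
#' pk <- pk_params()
#' meth_concentration(20, dose = 5, pk = pk)
pk_params <- function(tau_u = 8.25, tau_d = 57.5, tau_s = 10) {
  stopifnot(is.numeric(tau_u), is.numeric(tau_d), is.numeric(tau_s))
  if (!(tau_u > 0 && tau_d > 0 && tau_s > 0))
    stop("pk_params: all time constants must be strictly positive")
  if (tau_u == tau_d)
    stop("pk_params: tau_u must differ from tau_d (closed form is singular)")
  structure(list(tau_u = tau_u, tau_d = tau_d, tau_s = tau_s),
            class = "pk_params")
}

#' Temperature-dynamics parameters
#'
#' @param tau_T time constant of the body-temperature response, minutes
#' @param T0 baseline body temperature, degrees Celsius (must lie in the
#'   physiological window 30--42)
#' @return an object of class `thermo_params`
#' @export
thermo_params <- function(tau_T = 89.2, T0 = 37) {
  stopifnot(is.numeric(tau_T), is.numeric(T0))
  if (tau_T <= 0) stop("thermo_params: tau_T must be positive")
  if (T0 < 30 || T0 > 42)
    stop("thermo_params: T0 outside the physiological window [30, 42] degC")
  structure(list(tau_T = tau_T, T0 = T0), class = "thermo_params")
}

#' Circuit parameters
#'
#' All weights and basal excitabilities of the firing-rate network. The four
#' drug-sensitive parameters (`w_S`, `w_Exc`, `w_Inh`, `w_HD`) carry the
#' effect of orexin-receptor antagonist (SB) pretreatment; everything else is
#' held at the fixed published constants.
#'
#' Three circuit variants are supported:
#' \describe{
#'   \item{`base`}{HD receives only the direct drug input:
#'     `P_HD = sigmoid(w_HD * conc + gamma_HD)`.}
#'   \item{`gamma_hd`}{identical equations to `base`; the label marks that the
#'     SB-dependent parameter set is `(w_S, w_Exc, w_Inh, gamma_HD)` --
#'     antagonist pretreatment lowers the tonic inhibitory tone on HD instead
#'     of raising its drug sensitivity.}
#'   \item{`extended`}{the inhibitory tone on HD originates from the Inhib
#'     population: `P_HD = sigmoid(w_HD * conc + gamma_HD - w_Inh_HD * P_Inh)`.}
#' }
#'
#' `inhib_cap` is a hard ceiling on the Inhib activity used by the
#' inhibition-failure simulations (1 = intact, 0.5 = 50% inhibition,
#' 0 = Inhib silenced). With `inhib_cap = 1` the capped model reproduces the
#' uncapped model exactly.
#'
#' `recenter = TRUE` (default) subtracts the resting premotor drive so the
#' output is 0 degC at zero drug and zero stress with intact inhibition, and
#' the resting temperature equals `T0`. Set `recenter = FALSE` to use
#' `gamma_SPN` verbatim.
#'
#' @param w_S stress input amplitude, dimensionless
#' @param w_Exc,w_Inh,w_HD drug sensitivities of the Exc/Inhib/HD
#'   populations, per mg/kg (nonnegative)
#' @param gamma_Exc,gamma_Inh,gamma_HD basal excitabilities (sigmoid offsets)
#' @param w_Exc_Med,w_Inh_Med projection weights onto the medullary relay, degC
#' @param w_HD_SPN projection weight of HD onto the premotor output, degC
#' @param gamma_SPN basal premotor offset, degC
#' @param variant one of `"base"`, `"gamma_hd"`, `"extended"`
#' @param w_Inh_HD inhibitory projection weight Inhib -> HD (extended
#'   variant), nonnegative
#' @param inhib_cap maximal Inhib activity, in `[0, 1]`
#' @param recenter logical; recentre the premotor drive to zero at rest
#' @return an object of class `circuit_params`
#' @export
#' @examples
#' cp <- circuit_params(w_S = 2, w_Exc = 0.85, w_Inh = 1, w_HD = 0.8)
#' node_activities(t = 120, conc = 0, params = cp)
circuit_params <- function(w_S = 2.0, w_Exc = 0.85, w_Inh = 1.0, w_HD = 0.8,
                           gamma_Exc = -0.357, gamma_Inh = -1.335,
                           gamma_HD = -3.69,
                           w_Exc_Med = 9.89, w_Inh_Med = 6.38,
                           w_HD_SPN = 5.66, gamma_SPN = -3.35,
                           variant = c("base", "gamma_hd", "extended"),
                           w_Inh_HD = 5.0, inhib_cap = 1.0,
                           recenter = TRUE) {
  variant <- match.arg(variant)
  num <- c(w_S = w_S, w_Exc = w_Exc, w_Inh = w_Inh, w_HD = w_HD,
           gamma_Exc = gamma_Exc, gamma_Inh = gamma_Inh, gamma_HD = gamma_HD,
           w_Exc_Med = w_Exc_Med, w_Inh_Med = w_Inh_Med,
           w_HD_SPN = w_HD_SPN, gamma_SPN = gamma_SPN, w_Inh_HD = w_Inh_HD)
  if (any(!is.finite(num))) stop("circuit_params: all parameters must be finite")
  if (w_Exc < 0 || w_Inh < 0 || w_HD < 0)
    stop("circuit_params: drug sensitivities w_Exc, w_Inh, w_HD must be >= 0")
  if (w_Exc_Med < 0 || w_Inh_Med < 0 || w_HD_SPN < 0 || w_Inh_HD < 0)
    stop("circuit_params: projection weights must be nonnegative")
  if (inhib_cap < 0 || inhib_cap > 1)
    stop("circuit_params: inhib_cap must lie in [0, 1]")
  structure(c(as.list(num),
              list(variant = variant, inhib_cap = inhib_cap,
                   recenter = isTRUE(recenter))),
            class = "circuit_params")
}

#' Modify a parameter object
#'
#' Returns a copy of a `pk_params`, `thermo_params` or `circuit_params`
#' object with the named fields replaced, revalidating the result.
#'
#' @param params a parameter object
#' @param ... named replacements
#' @return a parameter object of the same class
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("update_params: replacements must be named")
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad))
    stop("update_params: unknown field(s): ", paste(bad, collapse = ", "))
  fields <- utils::modifyList(unclass(params), repl)
  ctor <- switch(class(params)[1],
                 pk_params = pk_params,
                 thermo_params = thermo_params,
                 circuit_params = circuit_params,
                 stop("update_params: unsupported class ", class(params)[1]))
  do.call(ctor, fields)
}

#' Injection schedule
#'
#' Timed dose events of an experiment: a pretreatment injection (SB or its
#' vehicle) followed by a treatment injection (methamphetamine or saline).
#' Both injections act as stress events; the drug enters the pharmacokinetic
#' model only through `meth_dose` at `meth_time`. SB itself has no
#' pharmacokinetics here -- its effect is a constant reparametrization of the
#' drug-sensitive circuit weights for the whole recording.
#'
#' @param meth_dose methamphetamine dose, mg/kg (>= 0; 0 = saline)
#' @param meth_time treatment injection time, minutes (convention: 0)
#' @param pretreat_time pretreatment injection time, minutes (convention: -30;
#'   must precede `meth_time`)
#' @param pretreat_label label of the pretreatment arm, e.g. `"vehicle"`,
#'   `"SB10"`, `"SB30"`
#' @param stress_times times of stress-evoking injections, minutes; defaults
#'   to both injections. Use `numeric(0)` for a stress-free scenario.
#' @return an object of class `injection_schedule`
#' @export
injection_schedule <- function(meth_dose = 0, meth_time = 0,
                               pretreat_time = -30,
                               pretreat_label = "vehicle",
                               stress_times = c(pretreat_time, meth_time)) {
  if (meth_dose < 0) stop("injection_schedule: doses must be nonnegative")
  if (pretreat_time >= meth_time)
    stop("injection_schedule: pretreatment must precede the treatment injection")
  structure(list(meth_dose = meth_dose, meth_time = meth_time,
                 pretreat_time = pretreat_time,
                 pretreat_label = as.character(pretreat_label),
                 stress_times = as.numeric(stress_times)),
            class = "injection_schedule")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("Pharmacokinetics: tau_u = %g min, tau_d = %g min, tau_s = %g min\n",
              x$tau_u, x$tau_d, x$tau_s))
  invisible(x)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("Circuit (%s variant)\n", x$variant))
  cat(sprintf("  drug-sensitive: w_S = %.3g, w_Exc = %.3g, w_Inh = %.3g, w_HD = %.3g\n",
              x$w_S, x$w_Exc, x$w_Inh, x$w_HD))
  cat(sprintf("  basal: gamma_Exc = %.3g, gamma_Inh = %.3g, gamma_HD = %.3g, gamma_SPN = %.3g\n",
              x$gamma_Exc, x$gamma_Inh, x$gamma_HD, x$gamma_SPN))
  cat(sprintf("  projections: Exc->Med %.3g, Inh->Med %.3g, HD->SPN %.3g",
              x$w_Exc_Med, x$w_Inh_Med, x$w_HD_SPN))
  if (x$variant == "extended") cat(sprintf(", Inh->HD %.3g", x$w_Inh_HD))
  cat("\n")
  if (x$inhib_cap < 1)
    cat(sprintf("  Inhib activity capped at %.0f%%\n", 100 * x$inhib_cap))
  invisible(x)
}
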