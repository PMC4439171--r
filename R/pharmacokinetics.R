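#' Blood methamphetamine concentration after an intraperitoneal injection
#'
#' Closed-form solution of the two-compartment absorption--elimination model:
#' the peritoneal depot empties with time constant `tau_u` and the blood
#' compartment is cleared with time constant `tau_d`, giving the
#' bi-exponential
#' \deqn{[M](t) = D\,(\tau_u/\tau_d - 1)^{-1}\,(e^{-t/\tau_u} - e^{-t/\tau_d})}
#' for `t > 0` and 0 for `t <= 0` (time measured from the injection).
#'
#' When `tau_u` and `tau_d` are within a relative 1e-6 of each other the
#' bi-exponential suffers catastrophic cancellation and the limiting form
#' `D (t/tau_u) exp(-t/tau_u)` is used instead.
#'
#' @param t time since the injection, minutes (vectorized; any real)
#' @param dose injected dose `D`, mg/kg (>= 0)
#' @param pk a [pk_params()] object
#' @return blood concentration in mg/kg, same length as `t`; nonnegative,
#'   continuous at `t = 0`, and linear in `dose`
#' @seealso [meth_concentration_ode()] for the direct numerical solution of
#'   the compartment system.
#' @export
#' @examples
#' pk <- pk_params()
#' tt <- seq(0, 180, by = 2)
#' conc <- meth_concentration(tt, dose = 5, pk = pk)
#' tt[which.max(conc)]   # peak near 18.7 min
meth_concentration <- function(t, dose, pk) {
  stopifnot(inherits(pk, "pk_params"))
  if (dose < 0) stop("meth_concentration: dose must be nonnegative")
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

#' Numerically integrated two-compartment drug concentration
#'
#' Solves the compartment system
#' \deqn{d[M_p]/dt = -[M_p]/\tau_u, \quad d[M]/dt = [M_p]/\tau_u - [M]/\tau_d}
#' with initial conditions `[M_p](0) = D`, `[M](0) = 0` using `deSolve`.
#' Serves as the independent numerical route against the closed form of
#' [meth_concentration()]; grid times at or before the injection return 0.
#'
#' @param t_grid strictly increasing vector of times, minutes (relative to
#'   the injection at 0)
#' @param dose injected dose, mg/kg
#' @param pk a [pk_params()] object
#' @param rtol,atol solver tolerances passed to [deSolve::ode()]
#' @return data.frame with columns `time`, `peritoneal`, `blood`
#' @export
meth_concentration_ode <- function(t_grid, dose, pk, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(diff(t_grid) <= 0))
    stop("meth_concentration_ode: t_grid must be strictly increasing")
  pos <- t_grid > 0
  res <- data.frame(time = t_grid,
                    peritoneal = ifelse(t_grid >= 0, dose * exp(-pmax(t_grid, 0) / pk$tau_u), 0),
                    blood = 0)
  if (any(pos)) {
    times <- c(0, t_grid[pos])
    deriv <- function(t, y, p) {
      list(c(-y[1] / p$tau_u, y[1] / p$tau_u - y[2] / p$tau_d))
    }
    sol <- deSolve::ode(y = c(Mp = dose, M = 0), times = times, func = deriv,
                        parms = pk, rtol = rtol, atol = atol)
    res$peritoneal[pos] <- sol[-1, "Mp"]
    res$blood[pos] <- sol[-1, "M"]
  }
  res
}

#' Injection-stress input
#'
#' Transient stress signal evoked by the handling and injection itself,
#' modeled as a single decaying exponential starting at the injection time:
#' `exp(-(t - t0)/tau_s)` for `t > t0` and 0 for `t <= t0`. The right-limit
#' at `t0` is 1 and the signal integrates to `tau_s` over `(t0, Inf)`.
#'
#' @param t time, minutes (vectorized)
#' @param t0 injection time, minutes
#' @param tau_s decay time constant, minutes (> 0)
#' @return dimensionless activity in `[0, 1]`
#' @export
stress_input <- function(t, t0, tau_s) {
  if (!is.numeric(tau_s) || tau_s <= 0)
    stop("stress_input: tau_s must be positive")
  ifelse(t > t0, exp(-(t - t0) / tau_s), 0)
}

# Summed (unscaled) stress input of every injection in a schedule.
total_stress <- function(t, schedule, pk) {
  s <- numeric(length(t))
  for (t0 in schedule$stress_times) s <- s + stress_input(t, t0, pk$tau_s)
  s
}
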