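#' Integrate the body-temperature ODE for a given drive signal
#'
#' Solves the first-order linear temperature equation
#' \deqn{\tau_T\, dT/dt = P(t) - (T - T_0)}
#' on a uniform fine grid with the classical fourth-order Runge--Kutta
#' update. Because the equation is linear in `T`, the RK4 step reduces to a
#' scalar linear recursion in `T - T0`, which is evaluated as a recursive
#' filter; the cost is a handful of vectorized operations per trajectory.
#' The equation is non-stiff at physiological time constants (~90 min), so a
#' fixed step of 0.1 min resolves it far below measurement precision.
#'
#' @param drive_fn function of time returning the premotor drive in degC;
#'   must accept a numeric vector
#' @param thermo a [thermo_params()] object
#' @param t_grid strictly increasing output times, minutes
#' @param t_start integration start (initial condition `T = T0`); defaults to
#'   `min(-50, t_grid[1])`
#' @param dt nominal integration step, minutes (the actual step divides each
#'   integration segment exactly and never exceeds `dt`)
#' @param events times at which the drive is discontinuous or kinked
#'   (injection times); integration is split there so the fourth-order
#'   accuracy survives the stress-input jumps
#' @return data.frame of class `temperature_trajectory` with columns
#'   `time_min`, `temp_c`
#' @export
#' @examples
#' th <- thermo_params()
#' # step drive of 2 degC: analytic response T0 + 2 (1 - exp(-t / tau_T))
#' tr <- temperature_from_drive(function(t) rep(2, length(t)), th,
#'                              t_grid = seq(0, 180, 2), t_start = 0)
temperature_from_drive <- function(drive_fn, thermo, t_grid,
                                   t_start = min(-50, t_grid[1]), dt = 0.1,
                                   events = numeric(0)) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (any(diff(t_grid) <= 0))
    stop("temperature_from_drive: t_grid must be strictly increasing")
  if (t_start > t_grid[1])
    stop("temperature_from_drive: integration must start at or before t_grid[1]")
  segs <- plan_segments(t_start, t_grid[length(t_grid)], dt, events)
  p <- lapply(segs, function(s) drive_fn(s$t_eval))
  if (any(!vapply(p, function(x) all(is.finite(x)), TRUE)))
    stop("temperature_from_drive: non-finite drive signal")
  sol <- propagate_segments(p, segs, thermo$tau_T)
  temp <- thermo$T0 + stats::approx(sol$t, sol$y, xout = t_grid)$y
  structure(data.frame(time_min = t_grid, temp_c = temp),
            class = c("temperature_trajectory", "data.frame"))
}

# Split [t_start, t_end] at the event times. Each segment gets a uniform
# half-step grid (full points at odd indices, midpoints even). The first
# evaluation point is nudged right by 1e-9 min so that a drive jumping AT the
# segment boundary is sampled on its own side (the stress input is defined by
# its left limit at the injection instant, but the integrand on [t0, t0+h]
# needs the right limit).
plan_segments <- function(t_start, t_end, dt, events = numeric(0)) {
  brk <- sort(unique(c(t_start, events[events > t_start & events < t_end],
                       t_end)))
  lapply(seq_len(length(brk) - 1L), function(i) {
    a <- brk[i]; b <- brk[i + 1L]
    n_steps <- max(1L, ceiling((b - a) / dt))
    h_t <- (b - a) / n_steps
    t_half <- a + (0:(2L * n_steps)) * (h_t / 2)
    t_eval <- t_half
    t_eval[1] <- t_eval[1] + 1e-9
    list(a = a, b = b, n_steps = n_steps, h_t = h_t,
         t_eval = t_eval, t_full = a + (0:n_steps) * h_t)
  })
}

# RK4 for the linear equation y' = (P(t) - y)/tau_T with y = T - T0 reduces
# to the recursion y_{k+1} = A y_k + c0 P_k + cm P_{k+1/2} + c1 P_{k+1},
# evaluated as a recursive filter. `p` holds the drive on the half-step grid
# (full points at odd indices); returns y on the full grid, starting at y0.
rk4_propagate <- function(p, n_steps, h_t, tau_T, y0 = 0) {
  h <- h_t / tau_T
  A <- 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24
  c0 <- (h / 6) * (1 - h + h^2 / 2 - h^3 / 4)
  cm <- (h / 6) * (4 - 2 * h + h^2 / 2)
  c1 <- h / 6
  k <- seq_len(n_steps)
  forcing <- c0 * p[2 * k - 1] + cm * p[2 * k] + c1 * p[2 * k + 1]
  c(y0, as.numeric(stats::filter(forcing, A, method = "recursive",
                                 init = y0)))
}

# Chain the RK4 recursion across segments; returns the concatenated full
# grid and the deviation y = T - T0 on it.
propagate_segments <- function(p, segs, tau_T) {
  t_all <- segs[[1]]$t_full
  y_all <- rk4_propagate(p[[1]], segs[[1]]$n_steps, segs[[1]]$h_t, tau_T)
  for (i in seq_along(segs)[-1]) {
    y <- rk4_propagate(p[[i]], segs[[i]]$n_steps, segs[[i]]$h_t, tau_T,
                       y0 = y_all[length(y_all)])
    t_all <- c(t_all, segs[[i]]$t_full[-1])
    y_all <- c(y_all, y[-1])
  }
  list(t = t_all, y = y_all)
}

#' Simulate the body-temperature response of the full model
#'
#' Composes the pharmacokinetic, stress and circuit components into the
#' premotor drive and integrates the temperature equation. Integration starts
#' at `t_start` (default -50 min, the start of the observation window) from
#' the baseline temperature `T0`.
#'
#' @param schedule an [injection_schedule()]
#' @param circuit a [circuit_params()] object
#' @param pk a [pk_params()] object
#' @param thermo a [thermo_params()] object
#' @param t_grid strictly increasing output times, minutes
#' @param t_start integration start, minutes
#' @param dt nominal integration step, minutes
#' @return a `temperature_trajectory` data.frame (`time_min`, `temp_c`)
#' @export
#' @examples
#' tr <- simulate_temperature(injection_schedule(meth_dose = 5),
#'                            circuit_params(), pk_params(), thermo_params(),
#'                            t_grid = seq(-50, 180, 2))
#' max(tr$temp_c)
simulate_temperature <- function(schedule, circuit, pk, thermo, t_grid,
                                 t_start = min(-50, t_grid[1]), dt = 0.1) {
  stopifnot(inherits(schedule, "injection_schedule"))
  drive_fn <- function(t) {
    conc <- meth_concentration(t - schedule$meth_time, schedule$meth_dose, pk)
    stress <- total_stress(t, schedule, pk)
    node_activities(t, conc, circuit, pk = pk, stress = stress)$P_SPN
  }
  temperature_from_drive(drive_fn, thermo, t_grid, t_start = t_start, dt = dt,
                         events = schedule_events(schedule))
}

# Times where the model drive is non-smooth: stress onsets (jumps) and the
# treatment injection (kink in the concentration curve).
schedule_events <- function(schedule) {
  sort(unique(c(schedule$stress_times,
                if (schedule$meth_dose > 0) schedule$meth_time)))
}

#' Steady-state temperature under a constant drive
#'
#' The fixed point of the temperature equation: `T0 + drive`.
#'
#' @param drive constant premotor drive, degC
#' @param thermo a [thermo_params()] object
#' @return temperature in degC
#' @export
steady_state_temperature <- function(drive, thermo) {
  stopifnot(inherits(thermo, "thermo_params"))
  thermo$T0 + drive
}

#' Write / read a temperature trajectory as delimited text
#'
#' Plain CSV with columns `time_min`, `temp_c`.
#'
#' @param trajectory a `temperature_trajectory`
#' @param path file path
#' @return `read_trajectory` returns a `temperature_trajectory`;
#'   `write_trajectory` returns `path` invisibly
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c("time_min", "temp_c")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "temp_c") %in% names(df)))
  structure(df[, c("time_min", "temp_c")],
            class = c("temperature_trajectory", "data.frame"))
}
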