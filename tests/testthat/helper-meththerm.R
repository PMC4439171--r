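# Shared fixtures: published fixed constants, reference truth weights, and a
# 2-SD cloud-separation check used by the recovery tests.

table1_pk <- function() pk_params(tau_u = 8.25, tau_d = 57.5, tau_s = 10)
table1_thermo <- function() thermo_params(tau_T = 89.2, T0 = 37)

vehicle_circuit <- function(...) {
  args <- utils::modifyList(as.list(scenario_truths()$vehicle), list(...))
  do.call(circuit_params, args)
}

std_grid <- function() seq(-50, 180, by = 2)

# iid noise exactly matching the fitting likelihood (no serial correlation,
# no per-animal offsets)
iid_noise <- function(sd = 0.3, seed = 42) {
  noise_spec(sd = sd, ar1 = 0, baseline_sd = 0, seed = seed)
}

# Are two posterior clouds disjoint at the 2-SD level in the projection onto
# the named parameter pair? Projects both sample clouds onto the direction
# connecting the means and compares the gap with the 2-SD radii.
clouds_disjoint_2sd <- function(e1, e2, pars) {
  m1 <- e1$mean[pars]; m2 <- e2$mean[pars]
  u <- (m2 - m1) / sqrt(sum((m2 - m1)^2))
  p1 <- as.matrix(e1$samples[, pars]) %*% u
  p2 <- as.matrix(e2$samples[, pars]) %*% u
  gap <- abs(mean(p2) - mean(p1))
  gap > 2 * stats::sd(p1) + 2 * stats::sd(p2)
}
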