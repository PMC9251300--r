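# Independent brute-force oracles and small fixtures shared by the tests.
# These deliberately re-derive the quantities with the most literal loops
# possible, so they stay independent of the package's vectorised/compiled
# paths.

# Double-loop Smoluchowski gain/loss over all ordered pairs, with the
# truncation that pairs whose combined size exceeds k_max never react.
oracle_smol_rhs <- function(n, q) {
  kmax <- length(n)
  gain <- numeric(kmax)
  loss <- numeric(kmax)
  for (i in seq_len(kmax)) {
    for (j in seq_len(kmax)) {
      if (i + j <= kmax) {
        rate <- q[i, j] * n[i] * n[j]
        gain[i + j] <- gain[i + j] + 0.5 * rate
        loss[i] <- loss[i] + rate
      }
    }
  }
  gain - loss
}

# Literal per-cell evaluation of the explicit upwind finite-volume update
# for one size class: fluxes at faces, zero at the boundaries.
oracle_upwind_step <- function(n, D_face, w_nodes, dz, dt) {
  nz <- length(n)
  flux <- numeric(nz + 1)
  for (f in 2:nz) {
    wf <- 0.5 * (w_nodes[f - 1] + w_nodes[f])
    nstar <- if (wf >= 0) n[f - 1] else n[f]
    flux[f] <- -D_face[f] * (n[f] - n[f - 1]) / dz + wf * nstar
  }
  out <- n
  for (i in seq_len(nz)) {
    out[i] <- n[i] + dt * (flux[i] - flux[i + 1]) / dz
  }
  out
}

# Forward-Euler integration of the reaction term alone through the exported
# RHS, used against the analytic constant-kernel solution.
euler_reaction <- function(n0_vec, km, dt, nsteps) {
  n <- n0_vec
  for (s in seq_len(nsteps)) {
    n <- n + dt * smoluchowski_rhs(n, km)
  }
  n
}

# Uniform single-regime water columns for well-mixed box experiments, at the
# measured regime maxima.
box_profiles <- function(z) {
  list(high_wind = env_profile(z, 25, 1e-3, 4e-4, "high_wind"),
       low_wind = env_profile(z, 25, 1e-5, 3e-7, "low_wind"))
}

box_config <- function(n0, days, dz = 0.5, dt = 30) {
  numerical_config(dz = dz, dt = dt, z_max = 1, h_ML = 1,
                   t_end = days * 86400, n0 = n0)
}

run_box <- function(table, n0, days, schedule = NULL, ...) {
  cfg <- box_config(n0, days)
  z <- config_nodes(cfg)
  run_simulation(cfg, table, profiles = box_profiles(z),
                 schedule = schedule, ...)
}

largest_appeared <- function(sim, threshold = 1) {
  reached <- which(apply(sim$diagnostics$N >= threshold, 1, any))
  if (length(reached)) max(reached) else 0L
}
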