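#' Numerical configuration of the water-column solver
#'
#' Collects the grid, time step, horizon, initial condition and stability
#' guards.  Defaults are the base-case numerics: 0.2 m cells over a 10 m
#' column with a 10 s explicit step; the `"fine"` preset halves both
#' (0.1 m, 5 s) for dispersion-sensitivity checks.
#'
#' @param dz Grid cell width (m). Default 0.2.
#' @param dt Time step (s). Default 10.
#' @param z_max Column depth (m); must be an integer multiple of `dz`.
#'   Default 10.
#' @param t_end Simulation horizon (s). Default 42 days.
#' @param h_ML Mixed-layer width (m), `<= z_max`. Default 3.
#' @param n0 Initial single-cell concentration in the mixed layer
#'   (colonies/m^3). Default 2.3e7.
#' @param output_every Diagnostics recording interval (s). Default 1 h.
#' @param snapshot_every Interval for storing full total-concentration
#'   profiles (s). Default 6 h.
#' @param guards List of stability guards: `reaction_guard` (largest allowed
#'   reaction loss fraction per step before internal sub-stepping, default
#'   0.1), `max_substeps` (default 10000), `enforce` (error on violated
#'   diffusion/Courant bounds, default `TRUE`).
#' @param preset `"base"` (use `dz`/`dt` as given) or `"fine"`
#'   (`dz = 0.1`, `dt = 5`).
#' @return An object of class `numerical_config`.
#' @export
numerical_config <- function(dz = 0.2, dt = 10, z_max = 10,
                             t_end = 42 * 86400, h_ML = 3, n0 = 2.3e7,
                             output_every = 3600, snapshot_every = 6 * 3600,
                             guards = list(), preset = c("base", "fine")) {
  preset <- match.arg(preset)
  if (preset == "fine") {
    dz <- 0.1
    dt <- 5
  }
  stopifnot(dz > 0, dt > 0, z_max > 0, t_end >= 0, n0 >= 0,
            output_every > 0, snapshot_every > 0)
  nz <- z_max / dz
  if (abs(nz - round(nz)) > 1e-8) {
    stop("z_max must be an integer multiple of dz")
  }
  if (h_ML > z_max || h_ML <= 0) stop("h_ML must lie in (0, z_max]")
  g <- list(reaction_guard = 0.1, max_substeps = 10000L, enforce = TRUE)
  g[names(guards)] <- guards
  structure(list(dz = dz, dt = dt, z_max = z_max, t_end = t_end,
                 h_ML = h_ML, n0 = n0, output_every = output_every,
                 snapshot_every = snapshot_every, guards = g,
                 nz = as.integer(round(nz))),
            class = "numerical_config")
}

#' @export
print.numerical_config <- function(x, ...) {
  cat(sprintf(
    "<numerical_config> dz = %g m, dt = %g s, z_max = %g m (%d cells), t_end = %.3g d\n",
    x$dz, x$dt, x$z_max, x$nz, x$t_end / 86400))
  cat(sprintf("  h_ML = %g m, n0 = %.3g colonies/m3, output every %.3g h\n",
              x$h_ML, x$n0, x$output_every / 3600))
  invisible(x)
}

#' Node depths of the simulation grid
#'
#' Cell centers at `(i - 1/2) dz`, positive downward, surface at `z = 0`.
#'
#' @param cfg A [numerical_config()].
#' @return Vector of node depths (m).
#' @export
config_nodes <- function(cfg) {
  (seq_len(cfg$nz) - 0.5) * cfg$dz
}

#' Initial simulation state
#'
#' Piecewise-uniform start: only single cells, at concentration `n0`
#' throughout the mixed layer and zero below; all larger classes empty.  The
#' cell-density field starts neutrally buoyant at the local water density
#' unless given explicitly.
#'
#' @param cfg A [numerical_config()].
#' @param table A [build_colony_table()] result.
#' @param env Optional `env_profile` used to set the neutral initial cell
#'   density; if `NULL`, a uniform 25 degC column is assumed.
#' @param rho_cell0 Optional initial cell density (kg/m^3), scalar or per
#'   node; overrides the neutral default.
#' @return An object of class `simulation_state`: list with clock `t` (s),
#'   concentration matrix `n[k, z]` (colonies/m^3) and `rho_cell[z]`
#'   (kg/m^3).
#' @export
initial_condition <- function(cfg, table, env = NULL, rho_cell0 = NULL) {
  stopifnot(inherits(cfg, "numerical_config"), inherits(table, "colony_table"))
  z <- config_nodes(cfg)
  n <- matrix(0, nrow(table), cfg$nz)
  n[1, z < cfg$h_ML] <- cfg$n0
  if (is.null(rho_cell0)) {
    temp <- if (is.null(env)) rep(25, cfg$nz) else env$temp_C
    rho_cell <- water_density(temp)
  } else {
    rho_cell <- rep_len(rho_cell0, cfg$nz)
  }
  structure(list(t = 0, n = n, rho_cell = rho_cell),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(
    "<simulation_state> t = %.4g d, %d size classes x %d cells, max n = %.3g colonies/m3\n",
    x$t / 86400, nrow(x$n), ncol(x$n), max(x$n)))
  invisible(x)
}

#' Upwinded face values of a node field
#'
#' Each interior face takes the value of the upstream node: the node above
#' when the face velocity is downward (`w >= 0`), the node below otherwise.
#' Boundary faces take the single adjacent node's value (their fluxes are
#' zeroed separately).
#'
#' @param n_nodes Node field (length `nz`).
#' @param w_face Face velocities (length `nz + 1`), positive downward.
#' @return Face values (length `nz + 1`).
#' @export
face_values <- function(n_nodes, w_face) {
  nz <- length(n_nodes)
  if (length(w_face) != nz + 1) stop("w_face must have length nz + 1")
  above <- c(n_nodes[1], n_nodes)   # node above each face
  below <- c(n_nodes, n_nodes[nz])  # node below each face
  ifelse(w_face >= 0, above, below)
}

#' Advective plus diffusive flux at cell faces
#'
#' `flux = -D (n_below - n_above) / dz + w n*`, positive downward, with the
#' upwinded face value `n*` from [face_values()].  The surface and bottom
#' faces carry exactly zero flux (no-flux boundaries: cells cannot leave the
#' water column).
#'
#' @param n_nodes Node field (length `nz`).
#' @param D_face Dispersion coefficient at faces (length `nz + 1`).
#' @param w_face Face velocities (length `nz + 1`), positive downward.
#' @param dz Grid cell width (m).
#' @return Fluxes at faces (length `nz + 1`).
#' @export
advective_diffusive_flux <- function(n_nodes, D_face, w_face, dz) {
  nz <- length(n_nodes)
  if (length(D_face) != nz + 1 || length(w_face) != nz + 1) {
    stop("face vectors must have length nz + 1")
  }
  nstar <- face_values(n_nodes, w_face)
  grad <- c(0, diff(n_nodes), 0) / dz
  flux <- -D_face * grad + w_face * nstar
  flux[1] <- 0
  flux[nz + 1] <- 0
  flux
}

# Arithmetic-mean interpolation of a node field onto faces; boundary faces
# copy the adjacent node (their fluxes are zero anyway).
nodes_to_faces <- function(v) {
  nz <- length(v)
  c(v[1], 0.5 * (v[-nz] + v[-1]), v[nz])
}

# Precompute everything that depends only on the environment profile and the
# colony table: face dispersion, water properties, the sticking-weighted
# static kernel (Brownian + shear) per depth, and the velocity prefactor
# A[k, z] with w = A * (rho_cell - rho_w).
precompute_regime <- function(profile, table, kernel_opts = list(),
                              g = 9.81) {
  ko <- list(shear_coeff = 4 / 3, settling_coeff = 1)
  ko[names(kernel_opts)] <- kernel_opts
  K <- nrow(table)
  nz <- length(profile$z_nodes)
  d <- table$d_m
  di <- matrix(d, K, K)
  dsum <- di + t(di)
  ai <- matrix(table$alpha, K, K)
  alpha <- pair_sticking(ai, t(ai), rule = attr(table, "sticking_rule"))
  br_base <- 2 * 1.38e-23 * dsum^2 / (3 * di * t(di))  # x T_K / mu
  ts_base <- ko$shear_coeff * dsum^3                   # x G
  T_K <- profile$temp_C + 273.15
  mu <- dynamic_viscosity(profile$temp_C)
  rho_w <- water_density(profile$temp_C)
  nu <- mu / rho_w
  G <- shear_rate(profile$eps, nu)
  ab <- array(0, dim = c(K, K, nz))
  for (z in seq_len(nz)) {
    ab[, , z] <- alpha * (br_base * (T_K[z] / mu[z]) + ts_base * G[z])
  }
  asett <- alpha * ko$settling_coeff * pi * dsum^2
  A <- outer(g * d^2 * table$vfrac / 18, 1 / (nu * rho_w))
  list(profile = profile, Dface = nodes_to_faces(profile$Dz),
       rho_w = rho_w, nu = nu, G = G, ab = ab, asett = asett, A = A,
       kernel_opts = ko)
}

# R-only reference implementation of one combined transport + reaction
# update, built from the exported face/flux/RHS operations.  Used by the
# tests as a cross-check of the compiled path and for small problems.
r_step_matrix <- function(n, pp, w, dz, dt, guard, max_substeps) {
  K <- nrow(n)
  nz <- ncol(n)
  trans <- matrix(0, K, nz)
  for (k in seq_len(K)) {
    w_face <- nodes_to_faces(w[k, ])
    flux <- advective_diffusive_flux(n[k, ], pp$Dface, w_face, dz)
    trans[k, ] <- (flux[-(nz + 1)] - flux[-1]) / dz
  }
  q_of <- function(z) {
    wz <- w[, z]
    pp$ab[, , z] + pp$asett * abs(outer(wz, wz, "-"))
  }
  ones <- matrix(1, K, K)
  rhs <- matrix(0, K, nz)
  lmax <- 0
  for (z in seq_len(nz)) {
    q <- q_of(z)
    rhs[, z] <- smoluchowski_rhs(n[, z], list(beta = q, alpha = ones))
    # loss-rate coefficients for the positivity guard
    M <- q * (outer(seq_len(K), seq_len(K), "+") <= K)
    lmax <- max(lmax, max(crossprod(M, n[, z])))
  }
  if (dt * lmax <= guard) {
    list(n = n + dt * (trans + rhs), substeps = 1L)
  } else {
    nsub <- ceiling(dt * lmax / guard)
    if (nsub > max_substeps) {
      stop("reaction requires ", nsub, " sub-steps (> max_substeps)")
    }
    out <- n + dt * trans
    dts <- dt / nsub
    for (s in seq_len(nsub)) {
      for (z in seq_len(nz)) {
        q <- q_of(z)
        out[, z] <- out[, z] +
          dts * smoluchowski_rhs(out[, z], list(beta = q, alpha = ones))
      }
    }
    list(n = out, substeps = as.integer(nsub))
  }
}

# Shared per-step update: light -> cell density -> velocities -> combined
# transport + reaction, all evaluated at the current time level.
step_core <- function(state, pp, cfg, light, density, use_compiled,
                      advection = TRUE) {
  z <- (seq_len(ncol(state$n)) - 0.5) * cfg$dz
  I <- light_at_depth(z, state$t, light)
  rho_cell <- update_cell_density(state$rho_cell, I, cfg$dt, density)
  K <- nrow(state$n)
  w <- if (advection) {
    pp$A * rep(rho_cell - pp$rho_w, each = K)
  } else {
    matrix(0, K, ncol(state$n))
  }
  res <- if (use_compiled) {
    cpp_step(state$n, pp$ab, pp$asett, w, pp$Dface, cfg$dz, cfg$dt,
             cfg$guards$reaction_guard, cfg$guards$max_substeps)
  } else {
    r_step_matrix(state$n, pp, w, cfg$dz, cfg$dt,
                  cfg$guards$reaction_guard, cfg$guards$max_substeps)
  }
  structure(list(t = state$t + cfg$dt, n = res$n, rho_cell = rho_cell,
                 substeps = res$substeps, w = w),
            class = "simulation_state")
}

#' Advance the simulation by one time step
#'
#' One explicit forward-in-time update of the full coupled system: the
#' light field and cell-density field are refreshed, buoyant velocities are
#' recomputed, and the combined finite-volume transport + Smoluchowski
#' reaction update is applied with the no-flux boundaries.  Column-
#' integrated cell mass is conserved.
#'
#' @param state A `simulation_state` (see [initial_condition()]).
#' @param env An `env_profile` on the simulation grid.
#' @param table A [build_colony_table()] result.
#' @param cfg A [numerical_config()].
#' @param light A [light_model()].
#' @param density A [cell_density_params()].
#' @param kernel_opts Optional list with `shear_coeff`, `settling_coeff`.
#' @param use_compiled Use the compiled step (default) or the pure-R
#'   reference path.
#' @param advection Set to `FALSE` to zero the buoyant velocities (the
#'   advection-off experiment); dispersion and reaction still act.
#' @return The advanced `simulation_state`.
#' @export
step_simulation <- function(state, env, table, cfg, light = light_model(),
                            density = cell_density_params(),
                            kernel_opts = list(), use_compiled = TRUE,
                            advection = TRUE) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(env, "env_profile"))
  if (length(env$z_nodes) != ncol(state$n)) {
    stop("environment grid does not match the state grid")
  }
  pp <- precompute_regime(env, table, kernel_opts)
  step_core(state, pp, cfg, light, density, use_compiled, advection)
}

#' Stability report for a configuration
#'
#' Checks the explicit-scheme stability numbers before a run: the diffusion
#' number `max(D) dt / dz^2` (must be <= 0.5), the Courant number
#' `max|w| dt / dz` (must be <= 1) with velocities evaluated at the
#' cell-density bounds, and an estimate of the reaction loss fraction per
#' step at the initial concentration (sub-stepped internally when above the
#' guard).
#'
#' @param cfg A [numerical_config()].
#' @param profiles List of `env_profile` objects the run will use.
#' @param table A [build_colony_table()] result.
#' @param density A [cell_density_params()].
#' @return An object of class `stability_report` with the three numbers and
#'   pass flags.
#' @export
stability_check <- function(cfg, profiles, table = build_colony_table(),
                            density = cell_density_params()) {
  stopifnot(inherits(cfg, "numerical_config"))
  if (inherits(profiles, "env_profile")) profiles <- list(profiles)
  D_max <- max(vapply(profiles, function(p) max(p$Dz), numeric(1)))
  w_max <- 0
  q_max <- 0
  for (p in profiles) {
    rho_w <- water_density(p$temp_C)
    nu <- kinematic_viscosity(p$temp_C)
    for (rho_c in c(density$rho_min, density$rho_max)) {
      rho_k <- outer(table$vfrac, rho_w, function(v, rw) rw + v * (rho_c - rw))
      w <- abs(stokes_velocity(matrix(table$d_m, nrow(table), length(rho_w)),
                               rho_k, matrix(rho_w, nrow(table),
                                             length(rho_w), byrow = TRUE),
                               matrix(nu, nrow(table), length(rho_w),
                                      byrow = TRUE)))
      w_max <- max(w_max, max(w))
    }
    km <- kernel_matrices(table, p$temp_C[which.max(p$eps)], max(p$eps),
                          keep_components = FALSE)
    q_max <- max(q_max, max(km$alpha * km$beta))
  }
  diff_number <- D_max * cfg$dt / cfg$dz^2
  courant <- w_max * cfg$dt / cfg$dz
  # crude stiffness estimate: loss fraction per step for the initial pool
  reaction_fraction <- q_max * cfg$n0 * nrow(table) * cfg$dt
  rep <- structure(list(diffusion_number = diff_number,
                        courant_number = courant,
                        reaction_fraction = reaction_fraction,
                        w_max = w_max, D_max = D_max,
                        diffusion_ok = diff_number <= 0.5,
                        courant_ok = courant <= 1),
                   class = "stability_report")
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> diffusion number %.3g (%s), Courant %.3g (%s)\n",
              x$diffusion_number, if (x$diffusion_ok) "ok" else "FAIL",
              x$courant_number, if (x$courant_ok) "ok" else "FAIL"))
  cat(sprintf("  max |w| = %.3g m/s, max D = %.3g m2/s, reaction loss fraction/step ~ %.3g\n",
              x$w_max, x$D_max, x$reaction_fraction))
  invisible(x)
}

assert_stable <- function(report) {
  if (!report$diffusion_ok) {
    stop(sprintf("diffusion number %.3g exceeds 0.5; reduce dt or D",
                 report$diffusion_number))
  }
  if (!report$courant_ok) {
    stop(sprintf("Courant number %.3g exceeds 1; reduce dt",
                 report$courant_number))
  }
  invisible(report)
}

#' Run a full water-column simulation
#'
#' Advances the coupled aggregation-transport system from `t = 0` to
#' `cfg$t_end`, swapping environment profiles according to the wind-regime
#' schedule and recording diagnostics at regular intervals.  The run is
#' fully deterministic: identical inputs give identical outputs.
#'
#' @param cfg A [numerical_config()].
#' @param table A [build_colony_table()] result.
#' @param profiles Named list of `env_profile` objects on the simulation
#'   grid.  Default: synthetic `high_wind` and `low_wind` profiles.
#' @param schedule A [scenario_schedule()]. Default: constant high wind.
#' @param light A [light_model()].
#' @param density A [cell_density_params()].
#' @param rho_cell0 Optional initial cell density (kg/m^3); default neutral.
#' @param kernel_opts Optional list with `shear_coeff`, `settling_coeff`.
#' @param use_compiled Use the compiled core (default).
#' @param advection Set to `FALSE` to zero the buoyant velocities for the
#'   whole run (the advection-off experiment).
#' @param verbose Print a progress line at each output interval.
#' @return A list of class `hab_simulation` with elements `diagnostics`
#'   (a `diagnostics_series`, see [cell_count()] and friends), `state`
#'   (final `simulation_state`), `stability` (the pre-run
#'   [stability_check()] report) and the inputs used.
#' @examples
#' \donttest{
#' cfg <- numerical_config(dz = 0.5, dt = 30, t_end = 86400)
#' sim <- run_simulation(cfg, build_colony_table(k_max = 25))
#' sim$diagnostics
#' }
#' @export
run_simulation <- function(cfg, table = build_colony_table(),
                           profiles = NULL, schedule = NULL,
                           light = light_model(),
                           density = cell_density_params(),
                           rho_cell0 = NULL, kernel_opts = list(),
                           use_compiled = TRUE, advection = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "numerical_config"), inherits(table, "colony_table"))
  z <- config_nodes(cfg)
  if (is.null(profiles)) {
    profiles <- list(high_wind = synthetic_profile(z, "high_wind",
                                                   h_ML = cfg$h_ML),
                     low_wind = synthetic_profile(z, "low_wind",
                                                  h_ML = cfg$h_ML))
  }
  if (is.null(schedule)) {
    schedule <- scenario_schedule("constant", names(profiles)[1])
  }
  missing_labs <- setdiff(unique(schedule$profiles), names(profiles))
  if (length(missing_labs) > 0) {
    stop("schedule references unknown profiles: ",
         paste(missing_labs, collapse = ", "))
  }
  for (p in profiles) {
    if (length(p$z_nodes) != cfg$nz) {
      stop("profile '", p$label, "' is not on the simulation grid")
    }
  }
  used <- unique(schedule$profiles)
  report <- stability_check(cfg, profiles[used], table, density)
  if (cfg$guards$enforce) assert_stable(report)
  prep <- lapply(profiles[used], precompute_regime, table = table,
                 kernel_opts = kernel_opts)

  env0 <- profiles[[scenario_label(0, schedule)]]
  state <- initial_condition(cfg, table, env = env0, rho_cell0 = rho_cell0)

  nsteps <- as.integer(round(cfg$t_end / cfg$dt))
  out_steps <- max(1L, as.integer(round(cfg$output_every / cfg$dt)))
  snap_steps <- max(1L, as.integer(round(cfg$snapshot_every / cfg$dt)))
  n_out <- nsteps %/% out_steps + 1L
  K <- nrow(table)
  times <- numeric(n_out)
  N <- matrix(0, K, n_out)
  mass <- numeric(n_out)
  courant <- numeric(n_out)
  snap_times <- numeric(0)
  snaps <- NULL
  kvec <- table$k

  record <- function(io, state, w) {
    times[io] <<- state$t
    Nk <- kvec * .rowSums(state$n, K, cfg$nz) * cfg$dz
    N[, io] <<- Nk
    mass[io] <<- sum(Nk)
    courant[io] <<- if (is.null(w)) 0 else max(abs(w)) * cfg$dt / cfg$dz
  }
  record(1L, state, NULL)
  snaps <- matrix(total_concentration(state$n), cfg$nz, 1)
  snap_times <- 0

  io <- 1L
  for (m in seq_len(nsteps)) {
    lab <- scenario_label(state$t, schedule)
    state <- step_core(state, prep[[lab]], cfg, light, density, use_compiled,
                       advection)
    if (m %% out_steps == 0L || m == nsteps) {
      if (m %% out_steps == 0L) {
        io <- io + 1L
        record(io, state, state$w)
      }
      if (anyNA(state$n) || any(!is.finite(state$n))) {
        stop(sprintf("non-finite concentrations at t = %.4g s", state$t))
      }
      if (min(state$n) < -1e-6 * max(abs(state$n))) {
        stop(sprintf("negative concentrations at t = %.4g s: min = %.3g",
                     state$t, min(state$n)))
      }
      if (verbose && m %% out_steps == 0L) {
        message(sprintf(
          "t = %6.2f d  mass rel. err = %.2e  Courant = %.3g  diff = %.3g",
          state$t / 86400, abs(mass[io] - mass[1]) / mass[1], courant[io],
          max(prep[[lab]]$profile$Dz) * cfg$dt / cfg$dz^2))
      }
    }
    if (m %% snap_steps == 0L) {
      snaps <- cbind(snaps, total_concentration(state$n))
      snap_times <- c(snap_times, state$t)
    }
  }
  io_used <- seq_len(io)
  diag <- structure(list(times = times[io_used],
                         N = N[, io_used, drop = FALSE],
                         mass = mass[io_used],
                         courant = courant[io_used],
                         C_snapshots = list(times = snap_times, C = snaps),
                         z_nodes = z, dz = cfg$dz, k_max = K),
                    class = "diagnostics_series")
  structure(list(diagnostics = diag, state = state, stability = report,
                 cfg = cfg, table = table, schedule = schedule,
                 light = light, density = density),
            class = "hab_simulation")
}

#' @export
print.hab_simulation <- function(x, ...) {
  d <- x$diagnostics
  rel <- abs(d$mass[length(d$mass)] - d$mass[1]) / d$mass[1]
  cat(sprintf("<hab_simulation> %.3g days, %d size classes, %d cells\n",
              x$state$t / 86400, d$k_max, length(d$z_nodes)))
  cat(sprintf("  mass balance rel. error %.2e; largest class with N_k >= 1: %s\n",
              rel, {
                reached <- which(apply(d$N >= 1, 1, any))
                if (length(reached)) max(reached) else "none"
              }))
  invisible(x)
}
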