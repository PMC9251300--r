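test_that("numerical configuration validates grid and presets", {
  cfg <- numerical_config()
  expect_equal(cfg$nz, 50)
  expect_equal(config_nodes(cfg)[1], 0.1)
  expect_equal(config_nodes(cfg)[50], 9.9)
  fine <- numerical_config(preset = "fine")
  expect_equal(c(fine$dz, fine$dt), c(0.1, 5))
  expect_error(numerical_config(dz = 0.3, z_max = 10), "integer multiple")
  expect_error(numerical_config(h_ML = 12), "h_ML")
})

test_that("initial condition puts single cells in the mixed layer only", {
  cfg <- numerical_config()
  tab <- build_colony_table(k_max = 10)
  st <- initial_condition(cfg, tab)
  z <- config_nodes(cfg)
  expect_equal(st$n[1, ], ifelse(z < 3, 2.3e7, 0))
  expect_equal(max(abs(st$n[-1, ])), 0)
  expect_equal(mass_audit(st$n, cfg$dz), 2.3e7 * 3)
  expect_equal(st$t, 0)
  # neutral start: no buoyant motion anywhere
  env <- synthetic_profile(z, "high_wind")
  st2 <- initial_condition(cfg, tab, env = env)
  expect_equal(velocity_profiles(st2$rho_cell, env, tab),
               matrix(0, 10, cfg$nz))
  # whole-column mixed layer gives a uniform field
  cfg2 <- numerical_config(h_ML = 10)
  expect_equal(initial_condition(cfg2, tab)$n[1, ], rep(2.3e7, 50))
})

test_that("face values upwind according to the face velocity sign", {
  n <- c(1, 2, 3, 4)
  wplus <- rep(1, 5)
  wminus <- rep(-1, 5)
  expect_equal(face_values(n, wplus), c(1, 1, 2, 3, 4))
  expect_equal(face_values(n, wminus), c(1, 2, 3, 4, 4))
  # mixed signs resolve per face; uniform field is sign-insensitive
  expect_equal(face_values(n, c(1, -1, 1, -1, 1)), c(1, 2, 2, 4, 4))
  expect_equal(face_values(rep(7, 4), wplus), face_values(rep(7, 4), wminus))
  expect_error(face_values(n, rep(1, 4)), "length")
})

test_that("fluxes combine Fickian diffusion with upwind advection and vanish at the boundaries", {
  dz <- 0.5
  Df <- rep(2e-3, 5)
  w0 <- rep(0, 5)
  # uniform field, no advection: all fluxes zero
  expect_equal(advective_diffusive_flux(rep(3, 4), Df, w0, dz), rep(0, 5))
  # linear profile: interior fluxes equal -D * slope
  n <- c(1, 2, 3, 4)
  fl <- advective_diffusive_flux(n, Df, w0, dz)
  expect_equal(fl[2:4], rep(-2e-3 * (1 / dz), 3))
  expect_equal(fl[c(1, 5)], c(0, 0))
  # advective part uses the upwinded face value
  fl2 <- advective_diffusive_flux(n, 0 * Df, rep(2, 5), dz)
  expect_equal(fl2, c(0, 2 * 1, 2 * 2, 2 * 3, 0))
})

test_that("one compiled step equals the R reference and the brute-force oracle", {
  set.seed(7)
  K <- 5
  nz <- 5
  dz <- 0.4
  dt <- 2
  n <- matrix(runif(K * nz) * 1e6, K, nz)
  w <- matrix(rnorm(K * nz) * 1e-4, K, nz)
  Dface <- c(0, runif(nz - 1) * 1e-3, 0)
  ab <- array(0, dim = c(K, K, nz))
  for (z in seq_len(nz)) {
    q <- matrix(runif(K * K), K, K) * 1e-11
    ab[, , z] <- (q + t(q)) / 2
  }
  asett <- matrix(0, K, K)
  res <- cyanoagg:::cpp_step(n, ab, asett, w, Dface, dz, dt, 0.1, 1000L)
  # R composition of the exported face/flux/RHS operations
  pp <- list(Dface = Dface, ab = ab, asett = asett)
  res_r <- cyanoagg:::r_step_matrix(n, pp, w, dz, dt, 0.1, 1000L)
  expect_equal(res$n, res_r$n, tolerance = 1e-12)
  # fully independent double-loop oracle, class by class and cell by cell
  trans <- t(vapply(seq_len(K), function(k) {
    oracle_upwind_step(n[k, ], Dface, w[k, ], dz, dt)
  }, numeric(nz)))
  react <- vapply(seq_len(nz), function(z) {
    oracle_smol_rhs(n[, z], ab[, , z])
  }, numeric(K))
  expect_equal(res$n, trans + dt * react, tolerance = 1e-12)
  # column cell mass unchanged by the step
  expect_equal(sum(seq_len(K) * rowSums(res$n)),
               sum(seq_len(K) * rowSums(n)), tolerance = 1e-12)
})

test_that("an advected pulse deepens by w*dt per step until boundary influence", {
  # single size class, ballasted cells, effectively no diffusion
  tab <- build_colony_table(k_max = 1)
  cfg <- numerical_config(dz = 0.1, dt = 100, z_max = 10, h_ML = 10,
                          t_end = 1e5)
  z <- config_nodes(cfg)
  env <- env_profile(z, 25, 1e-12, 0, "still")
  # frozen cell density: rates so small the Euler update cannot move it
  frozen <- cell_density_params(c1 = 1e-30, c2 = 1e-30)
  st <- initial_condition(cfg, tab, env = env, rho_cell0 = 1065)
  st$n[1, ] <- 0
  st$n[1, 20] <- 1e6  # pulse at ~2 m
  w <- velocity_profiles(st$rho_cell, env, tab)[1, 1]
  expect_gt(w, 0)
  com0 <- sum(z * st$n[1, ]) / sum(st$n[1, ])
  nsteps <- 500
  for (i in seq_len(nsteps)) {
    st <- step_simulation(st, env, tab, cfg, density = frozen)
  }
  com1 <- sum(z * st$n[1, ]) / sum(st$n[1, ])
  expect_equal(com1 - com0, w * cfg$dt * nsteps, tolerance = 1e-9)
  expect_equal(sum(st$n), 1e6, tolerance = 1e-10)
})

test_that("pure diffusion of a cosine mode converges to the analytic decay rate", {
  tab <- build_colony_table(k_max = 1)
  D <- 5e-4
  H <- 10
  rate_exact <- D * (pi / H)^2
  decay_error <- function(dz, dt, t_total = 4e4) {
    cfg <- numerical_config(dz = dz, dt = dt, z_max = H, h_ML = H,
                            t_end = t_total)
    z <- config_nodes(cfg)
    env <- env_profile(z, 25, D, 0, "diffusion")
    st <- initial_condition(cfg, tab, env = env)
    st$n[1, ] <- 1e5 * (1 + 0.5 * cos(pi * z / H))
    amp0 <- max(st$n[1, ]) - min(st$n[1, ])
    for (i in seq_len(round(t_total / dt))) {
      st <- step_simulation(st, env, tab, cfg, advection = FALSE)
    }
    amp1 <- max(st$n[1, ]) - min(st$n[1, ])
    rate_num <- -log(amp1 / amp0) / t_total
    abs(rate_num - rate_exact) / rate_exact
  }
  err_coarse <- decay_error(1, 50)
  err_fine <- decay_error(0.5, 12.5)
  expect_lt(err_fine, err_coarse / 2)
  expect_lt(err_fine, 0.05)
})

test_that("stability report computes the textbook numbers and gates the run", {
  cfg <- numerical_config()  # dz = 0.2, dt = 10
  z <- config_nodes(cfg)
  tab <- build_colony_table(k_max = 10)
  ok <- env_profile(z, 25, 1e-3, 4e-4, "ok")
  rep1 <- stability_check(cfg, ok, tab)
  expect_equal(rep1$diffusion_number, 1e-3 * 10 / 0.04)
  expect_true(rep1$diffusion_ok && rep1$courant_ok)
  bad <- env_profile(z, 25, 5e-3, 4e-4, "bad")
  rep2 <- stability_check(cfg, bad, tab)
  expect_equal(rep2$diffusion_number, 1.25)
  expect_false(rep2$diffusion_ok)
  expect_error(run_simulation(cfg, tab, profiles = list(bad = bad)),
               "diffusion number")
  # Courant example: w = 1e-3 m/s, dt = 10, dz = 0.2 -> 0.05
  expect_equal(1e-3 * cfg$dt / cfg$dz, 0.05)
})

test_that("runs are deterministic and compose from single steps", {
  tab <- build_colony_table(k_max = 12)
  cfg <- numerical_config(dz = 0.5, dt = 30, t_end = 6 * 3600, n0 = 1e8)
  sim1 <- run_simulation(cfg, tab)
  sim2 <- run_simulation(cfg, tab)
  expect_identical(sim1$diagnostics, sim2$diagnostics)
  expect_identical(sim1$state$n, sim2$state$n)
  # t_end = 0: diagnostics hold only the initial condition
  cfg0 <- numerical_config(dz = 0.5, dt = 30, t_end = 0)
  sim0 <- run_simulation(cfg0, tab)
  expect_equal(sim0$diagnostics$times, 0)
  expect_equal(sim0$diagnostics$mass, 2.3e7 * 3)
  # the run loop is exactly repeated application of step_simulation
  z <- config_nodes(cfg)
  env <- synthetic_profile(z, "high_wind", h_ML = cfg$h_ML)
  st <- initial_condition(cfg, tab, env = env)
  for (i in 1:20) st <- step_simulation(st, env, tab, cfg)
  cfg20 <- cfg
  cfg20$t_end <- 20 * cfg$dt
  sim20 <- run_simulation(cfg20, tab, profiles = list(high_wind = env))
  expect_equal(sim20$state$n, st$n, tolerance = 1e-13)
  expect_equal(sim20$state$rho_cell, st$rho_cell)
})

test_that("compiled and R reference paths agree along a short trajectory", {
  tab <- build_colony_table(k_max = 8)
  cfg <- numerical_config(dz = 1, dt = 60, t_end = 1800, n0 = 1e8)
  simC <- run_simulation(cfg, tab, use_compiled = TRUE)
  simR <- run_simulation(cfg, tab, use_compiled = FALSE)
  expect_equal(simC$state$n, simR$state$n, tolerance = 1e-10)
})

test_that("halving the grid and time step shifts appearance times only modestly", {
  tab <- build_colony_table(k_max = 25)
  cfg_c <- numerical_config(dz = 0.5, dt = 30, t_end = 8 * 86400, n0 = 1e8)
  cfg_f <- numerical_config(dz = 0.25, dt = 15, t_end = 8 * 86400, n0 = 1e8)
  tau_c <- appearance_time(run_simulation(cfg_c, tab)$diagnostics, 25)
  tau_f <- appearance_time(run_simulation(cfg_f, tab)$diagnostics, 25)
  expect_false(is.na(tau_c) || is.na(tau_f))
  # first-order upwinding is numerically dispersive; refinement may shift
  # appearance times, but only by a bounded fraction
  expect_lt(abs(tau_f / tau_c - 1), 0.2)
})

test_that("turning advection off leaves appearance times approximately unchanged", {
  tab <- build_colony_table(k_max = 25)
  cfg <- numerical_config(dz = 0.5, dt = 30, t_end = 8 * 86400, n0 = 1e8)
  tau_on <- appearance_time(run_simulation(cfg, tab)$diagnostics, 25)
  tau_off <- appearance_time(
    run_simulation(cfg, tab, advection = FALSE)$diagnostics, 25)
  expect_false(is.na(tau_on) || is.na(tau_off))
  expect_lt(abs(tau_off / tau_on - 1), 0.2)
})
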