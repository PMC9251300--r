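test_that("water properties follow the standard freshwater correlations", {
  expect_equal(water_density(4), 1000, tolerance = 1e-3)
  expect_equal(water_density(25), 997.05, tolerance = 1e-4)
  expect_gt(water_density(10), water_density(25))
  expect_gt(water_density(4), water_density(30))
  expect_error(water_density(45), "range")

  expect_equal(dynamic_viscosity(20), 1.002e-3, tolerance = 0.02)
  expect_gt(dynamic_viscosity(20), dynamic_viscosity(30))
  expect_equal(kinematic_viscosity(20), 1.0e-6, tolerance = 0.03)
  expect_error(dynamic_viscosity(-1), "range")
})

test_that("shear rate is the square root of dissipation over viscosity", {
  expect_equal(shear_rate(4e-4, 1e-6), 20)
  expect_equal(shear_rate(0, 1e-6), 0)
  expect_equal(shear_rate(3e-7, 1e-6), sqrt(0.3), tolerance = 1e-12)
  expect_error(shear_rate(1e-6, 0), "positive")
})

test_that("synthetic profiles pin the regime maxima and keep their floors", {
  z <- seq(0.1, 9.9, by = 0.2)
  hi <- synthetic_profile(z, "high_wind")
  lo <- synthetic_profile(z, "low_wind")
  expect_equal(max(hi$eps), 4e-4)
  expect_equal(max(lo$eps), 3e-7)
  expect_equal(max(hi$Dz), 1e-3)
  expect_true(all(hi$Dz >= 1e-6) && all(lo$Dz >= 1e-6))
  expect_true(all(hi$eps >= 0))
  # stratified: warm epilimnion above cold hypolimnion
  expect_gt(hi$temp_C[1], hi$temp_C[length(z)])
  expect_true(all(diff(hi$temp_C) <= 0))
  # mixed layer holds the maxima throughout
  expect_true(all(hi$eps[z <= 3] == 4e-4))
  expect_error(synthetic_profile(z, "high_wind", h_ML = 20), "inside")
  # kelvin accessor
  expect_equal(profile_temp_K(hi), hi$temp_C + 273.15)
})

test_that("profile files are read, interpolated, and validated", {
  z <- seq(0.25, 9.75, by = 0.5)
  f <- tempfile(fileext = ".csv")
  writeLines(c("depth_m,temp_C,Dz_m2s,eps_m2s3",
               "0,25,1e-3,4e-4",
               "10,11,1e-6,1e-9"), f)
  p <- read_profile_table(f, z)
  expect_s3_class(p, "env_profile")
  # linear interpolation at mid-depth
  expect_equal(p$temp_C[which.min(abs(z - 5))], 25 + (11 - 25) * 0.475,
               tolerance = 1e-12)
  # file deeper than the grid: truncated without error
  p2 <- read_profile_table(f, z[z < 5])
  expect_equal(length(p2$Dz), sum(z < 5))
  # constant extrapolation when the file is shallower than the grid
  writeLines(c("depth_m,temp_C,Dz_m2s,eps_m2s3",
               "2,20,1e-4,1e-6",
               "4,15,1e-5,1e-8"), f)
  p3 <- read_profile_table(f, z)
  expect_equal(p3$temp_C[1], 20)
  expect_equal(p3$temp_C[length(z)], 15)
  # round trip through write/read on the same grid
  hi <- synthetic_profile(z, "high_wind")
  utils::write.csv(data.frame(depth_m = z, temp_C = hi$temp_C,
                              Dz_m2s = hi$Dz, eps_m2s3 = hi$eps),
                   f, row.names = FALSE)
  back <- read_profile_table(f, z)
  expect_equal(back$Dz, hi$Dz, tolerance = 1e-10)
  # invalid tables are rejected with the offending location named
  writeLines(c("depth_m,temp_C,Dz_m2s,eps_m2s3",
               "0,25,1e-3,4e-4",
               "5,20,1e-4,-1e-6"), f)
  expect_error(read_profile_table(f, z), "negative eps.*row 2")
  writeLines(c("depth_m,temp_C,Dz_m2s",
               "0,25,1e-3"), f)
  expect_error(read_profile_table(f, z), "missing columns")
  writeLines(c("depth_m,temp_C,Dz_m2s,eps_m2s3",
               "5,25,1e-3,4e-4",
               "2,20,1e-4,1e-6"), f)
  expect_error(read_profile_table(f, z), "increasing")
})

test_that("wind schedules alternate stepwise with an even duty cycle", {
  sc <- scenario_schedule("constant", "high_wind")
  expect_equal(scenario_label(c(0, 1e6), sc), rep("high_wind", 2))
  sd <- scenario_schedule("alternating", c("high_wind", "low_wind"),
                          period = 86400)
  expect_equal(scenario_label(36 * 3600, sd), "low_wind")
  expect_equal(scenario_label(0, sd), "high_wind")
  expect_equal(scenario_label(2 * 86400, sd), "high_wind")
  # over whole periods, exactly half the time in each regime
  t <- seq(0, 42 * 86400 - 1, by = 60)
  labs <- scenario_label(t, sd)
  expect_equal(mean(labs == "high_wind"), 0.5)
  # profile lookup resolves labels
  z <- seq(0.25, 9.75, by = 0.5)
  pr <- list(high_wind = synthetic_profile(z, "high_wind"),
             low_wind = synthetic_profile(z, "low_wind"))
  expect_equal(scenario_profile(1.5 * 86400, sd, pr)$label, "low_wind")
  expect_error(scenario_profile(0, sd, pr["high_wind"]), "unknown profiles")
  expect_error(scenario_schedule("alternating", c("a", "b")), "period")
  expect_error(scenario_schedule("constant", c("a", "b")), "one profile")
})

test_that("the diel light field is a truncated half-sine attenuated with depth", {
  lm <- light_model()
  expect_equal(surface_light(8 * 3600, lm), 800)     # midday of a 16 h photoperiod
  expect_equal(surface_light(0, lm), 0)              # dawn
  expect_equal(surface_light(17 * 3600, lm), 0)      # dark phase
  expect_equal(surface_light(24 * 3600 + 8 * 3600, lm), 800)  # periodic
  t <- seq(0, 48 * 3600, by = 600)
  I <- surface_light(t, lm)
  expect_true(all(I >= 0 & I <= 800))
  # Beer-Lambert: half value at ln(2)/k_I at peak, monotone in depth
  expect_equal(light_at_depth(log(2) / 1.3, 8 * 3600, lm), 400)
  z <- seq(0, 10, by = 0.1)
  expect_true(all(diff(light_at_depth(z, 8 * 3600, lm)) <= 0))
  expect_equal(light_at_depth(z, 20 * 3600, lm), rep(0, length(z)))
  expect_equal(light_at_depth(0, 4 * 3600, lm), surface_light(4 * 3600, lm))
})
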