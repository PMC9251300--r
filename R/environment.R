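#' Density of fresh water
#'
#' Standard polynomial correlation in temperature (Millero-Poisson zero-
#' salinity limit); maximum near 4 degC.
#'
#' @param temp_C Water temperature (degC), `0 < temp_C < 40`; vectorised.
#' @return Density (kg/m^3).
#' @export
water_density <- function(temp_C) {
  if (any(temp_C <= 0 | temp_C >= 40)) {
    stop("temperature out of supported range (0, 40) degC")
  }
  999.842594 + 6.793952e-2 * temp_C - 9.095290e-3 * temp_C^2 +
    1.001685e-4 * temp_C^3 - 1.120083e-6 * temp_C^4 + 6.536332e-9 * temp_C^5
}

#' Dynamic viscosity of water
#'
#' Vogel-type correlation `mu = A * 10^(B / (T_K - C))`; about 1.00e-3 Pa s
#' at 20 degC and strictly decreasing with temperature.
#'
#' @param temp_C Water temperature (degC), `0 < temp_C < 40`; vectorised.
#' @return Dynamic viscosity (Pa s).
#' @export
dynamic_viscosity <- function(temp_C) {
  if (any(temp_C <= 0 | temp_C >= 40)) {
    stop("temperature out of supported range (0, 40) degC")
  }
  T_K <- temp_C + 273.15
  2.414e-5 * 10^(247.8 / (T_K - 140))
}

#' Kinematic viscosity of water
#'
#' `nu = mu / rho`; about 1.0e-6 m^2/s at 20 degC.
#'
#' @inheritParams dynamic_viscosity
#' @return Kinematic viscosity (m^2/s).
#' @export
kinematic_viscosity <- function(temp_C) {
  dynamic_viscosity(temp_C) / water_density(temp_C)
}

#' Turbulent shear rate
#'
#' `G = sqrt(eps / nu)`, where `eps` is the turbulent-kinetic-energy
#' dissipation rate and `nu` the kinematic viscosity.
#'
#' @param eps Dissipation rate (m^2/s^3), `>= 0`; vectorised.
#' @param nu Kinematic viscosity (m^2/s), `> 0`.
#' @return Shear rate (1/s).
#' @export
shear_rate <- function(eps, nu) {
  if (any(nu <= 0)) stop("kinematic viscosity must be positive")
  if (any(eps < 0)) stop("dissipation rate must be non-negative")
  sqrt(eps / nu)
}

#' Construct a water-column profile from vectors
#'
#' Low-level constructor for an environment profile on the simulation grid;
#' use [synthetic_profile()] for the built-in stratified regimes or
#' [read_profile_table()] to load one from file.
#'
#' @param z_nodes Node depths (m, positive downward, surface at 0).
#' @param temp_C Water temperature (degC), in (0, 40].
#' @param Dz Combined molecular + turbulent dispersion (m^2/s), positive.
#' @param eps Turbulent-kinetic-energy dissipation rate (m^2/s^3),
#'   non-negative.
#' @param label Regime name.
#' @return An object of class `env_profile`.
#' @export
env_profile <- function(z_nodes, temp_C, Dz, eps, label = "custom") {
  new_env_profile(z_nodes, rep_len(temp_C, length(z_nodes)),
                  rep_len(Dz, length(z_nodes)),
                  rep_len(eps, length(z_nodes)), label)
}

new_env_profile <- function(z_nodes, temp_C, Dz, eps, label) {
  n <- length(z_nodes)
  if (length(temp_C) != n || length(Dz) != n || length(eps) != n) {
    stop("profile vectors must all share the grid length")
  }
  if (any(Dz <= 0)) stop("dispersion coefficient must be positive everywhere")
  if (any(eps < 0)) stop("dissipation rate must be non-negative everywhere")
  if (any(temp_C <= 0 | temp_C > 40)) {
    stop("temperature must lie in (0, 40] degC")
  }
  structure(list(z_nodes = z_nodes, temp_C = temp_C, Dz = Dz, eps = eps,
                 label = label),
            class = "env_profile")
}

#' @export
print.env_profile <- function(x, ...) {
  cat(sprintf(
    "<env_profile> '%s': %d nodes, z in [%.2f, %.2f] m\n",
    x$label, length(x$z_nodes), min(x$z_nodes), max(x$z_nodes)))
  cat(sprintf("  T %.1f-%.1f degC, Dz max %.2g m2/s, eps max %.2g m2/s3\n",
              min(x$temp_C), max(x$temp_C), max(x$Dz), max(x$eps)))
  invisible(x)
}

#' Temperature of a profile in kelvin
#'
#' @param profile An `env_profile`.
#' @return Vector of absolute temperatures (K).
#' @export
profile_temp_K <- function(profile) {
  profile$temp_C + 273.15
}

#' Synthetic stratified water-column profile
#'
#' Builds a smooth two-layer (tanh) stand-in for a summer dimictic lake:
#' warm epilimnion over cold hypolimnion, with dispersion and dissipation at
#' their mixed-layer maxima above `h_ML` and rolling off to background values
#' below.  The regime presets pin the dissipation maxima at the field-measured
#' values (high wind: 4e-4 m^2/s^3 at ~8 m/s winds; low wind: 3e-7 m^2/s^3 at
#' ~2 m/s winds) and use mixed-layer dispersion maxima of 1e-3 and 1e-5
#' m^2/s, inside the 1e-6 to 1e-2 m^2/s range typical of lakes.
#'
#' @param z_nodes Node depths (m, positive downward, surface at 0).
#' @param regime `"high_wind"` or `"low_wind"`; sets defaults for `eps_max`
#'   and `D_max`.
#' @param h_ML Mixed-layer (epilimnion) depth (m). Default 3.
#' @param T_epi,T_hypo Epilimnion and hypolimnion temperatures (degC).
#' @param eps_max Mixed-layer dissipation maximum (m^2/s^3); regime default.
#' @param D_max Mixed-layer dispersion maximum (m^2/s); regime default.
#' @param D_background Deep-water dispersion floor (m^2/s). Default 1e-6
#'   (molecular scale).
#' @param eps_background Deep-water dissipation floor (m^2/s^3). Default
#'   1e-10.
#' @param thermocline_width Half-width of the tanh transition (m). Default 1.
#' @param label Regime label stored on the profile.
#' @return An `env_profile`.
#' @examples
#' z <- seq(0.1, 9.9, by = 0.2)
#' hi <- synthetic_profile(z, "high_wind")
#' max(hi$eps)  # 4e-4 by construction
#' @export
synthetic_profile <- function(z_nodes, regime = c("high_wind", "low_wind"),
                              h_ML = 3, T_epi = 25, T_hypo = 12,
                              eps_max = NULL, D_max = NULL,
                              D_background = 1e-6, eps_background = 1e-10,
                              thermocline_width = 1, label = NULL) {
  regime <- match.arg(regime)
  if (is.null(eps_max)) {
    eps_max <- switch(regime, high_wind = 4e-4, low_wind = 3e-7)
  }
  if (is.null(D_max)) {
    D_max <- switch(regime, high_wind = 1e-3, low_wind = 1e-5)
  }
  if (is.null(label)) label <- regime
  if (h_ML <= 0 || h_ML >= max(z_nodes)) {
    stop("mixed-layer depth must lie inside the water column")
  }
  if (T_hypo >= T_epi) stop("epilimnion must be warmer than the hypolimnion")
  if (eps_max < eps_background || D_max < D_background) {
    stop("mixed-layer maxima must be at least the background values")
  }
  # tanh step centered one transition width below the mixed layer
  z_c <- h_ML + thermocline_width
  s <- 0.5 * (1 - tanh((z_nodes - z_c) / thermocline_width))
  temp_C <- T_hypo + (T_epi - T_hypo) * s
  mixed <- z_nodes <= h_ML
  Dz <- D_background + (D_max - D_background) * s
  eps <- eps_background + (eps_max - eps_background) * s
  # pin the mixed layer exactly at the regime maxima
  Dz[mixed] <- D_max
  eps[mixed] <- eps_max
  new_env_profile(z_nodes, temp_C, Dz, eps, label)
}

#' Read a water-column profile from delimited text
#'
#' Expects a CSV (or other delimiter) with header columns `depth_m`,
#' `temp_C`, `Dz_m2s`, `eps_m2s3` and strictly increasing depths.  Values are
#' linearly interpolated onto the requested grid nodes, with constant
#' extrapolation beyond the file's depth range.
#'
#' @param path Path to the profile table.
#' @param z_nodes Node depths (m) of the simulation grid.
#' @param sep Field separator. Default `","`.
#' @param label Label for the profile; defaults to the file name.
#' @return An `env_profile` on `z_nodes`.
#' @export
read_profile_table <- function(path, z_nodes, sep = ",", label = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("depth_m", "temp_C", "Dz_m2s", "eps_m2s3")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("profile table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) < 2) stop("profile table needs at least two rows")
  if (any(diff(raw$depth_m) <= 0)) {
    bad <- which(diff(raw$depth_m) <= 0)[1] + 1
    stop("profile depths must be strictly increasing (row ", bad, ")")
  }
  for (col in c("Dz_m2s", "eps_m2s3")) {
    if (any(raw[[col]] < 0)) {
      bad <- which(raw[[col]] < 0)[1]
      stop("negative ", col, " in profile table (row ", bad, ")")
    }
  }
  interp <- function(v) {
    stats::approx(raw$depth_m, v, xout = z_nodes, rule = 2)$y
  }
  if (is.null(label)) label <- basename(path)
  new_env_profile(z_nodes, interp(raw$temp_C), interp(raw$Dz_m2s),
                  interp(raw$eps_m2s3), label)
}

#' Wind-regime schedule
#'
#' Either a single constant regime or stepwise alternation between two
#' regimes with a 50/50 duty cycle (e.g. daily or hourly switching).
#'
#' @param mode `"constant"` or `"alternating"`.
#' @param profiles Character vector of regime labels: one for constant mode,
#'   two for alternating mode.
#' @param period Switching period (s) for alternating mode (time spent in
#'   each regime before switching).
#' @return An object of class `scenario_schedule`.
#' @examples
#' scenario_schedule("alternating", c("high_wind", "low_wind"),
#'                   period = 86400)
#' @export
scenario_schedule <- function(mode = c("constant", "alternating"),
                              profiles, period = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (length(profiles) != 1) stop("constant mode takes one profile label")
  } else {
    if (length(profiles) != 2) stop("alternating mode takes two profile labels")
    if (is.null(period) || period <= 0) {
      stop("alternating mode needs a positive period")
    }
  }
  structure(list(mode = mode, profiles = profiles, period = period),
            class = "scenario_schedule")
}

#' @export
print.scenario_schedule <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<scenario_schedule> constant '%s'\n", x$profiles[1]))
  } else {
    cat(sprintf("<scenario_schedule> alternating %s <-> %s every %.3g h\n",
                x$profiles[1], x$profiles[2], x$period / 3600))
  }
  invisible(x)
}

#' Active regime label at a given time
#'
#' @param t Time (s); vectorised.
#' @param schedule A [scenario_schedule()].
#' @return Character vector of regime labels.
#' @export
scenario_label <- function(t, schedule) {
  stopifnot(inherits(schedule, "scenario_schedule"))
  if (schedule$mode == "constant") {
    rep(schedule$profiles[1], length(t))
  } else {
    idx <- (floor(t / schedule$period) %% 2) + 1
    schedule$profiles[idx]
  }
}

#' Profile in force at a given time
#'
#' @param t Time (s), scalar.
#' @param schedule A [scenario_schedule()].
#' @param profiles Named list of `env_profile` objects keyed by the labels
#'   the schedule references.
#' @return The active `env_profile`.
#' @export
scenario_profile <- function(t, schedule, profiles) {
  lab <- scenario_label(t, schedule)
  missing_labs <- setdiff(unique(schedule$profiles), names(profiles))
  if (length(missing_labs) > 0) {
    stop("schedule references unknown profiles: ",
         paste(missing_labs, collapse = ", "))
  }
  profiles[[lab]]
}

#' Diel surface-light model
#'
#' Surface irradiance follows a half-sine over the photoperiod and is zero
#' for the remainder of the diel cycle; irradiance decays exponentially with
#' depth (Beer-Lambert).
#'
#' @param I_max Peak surface irradiance (W/m^2). Default 800.
#' @param D_L Photoperiod (s). Default 16 h.
#' @param day_length Diel period (s). Default 24 h.
#' @param k_I Light attenuation coefficient (1/m). Default 1.3.
#' @return An object of class `light_model`.
#' @export
light_model <- function(I_max = 800, D_L = 16 * 3600,
                        day_length = 24 * 3600, k_I = 1.3) {
  stopifnot(I_max >= 0, D_L > 0, D_L <= day_length, k_I > 0)
  structure(list(I_max = I_max, D_L = D_L, day_length = day_length, k_I = k_I),
            class = "light_model")
}

#' @export
print.light_model <- function(x, ...) {
  cat(sprintf(
    "<light_model> I_max = %g W/m2, photoperiod %.3g h of %.3g h, k_I = %g 1/m\n",
    x$I_max, x$D_L / 3600, x$day_length / 3600, x$k_I))
  invisible(x)
}

#' Surface irradiance at a given time
#'
#' @param t Time since dawn of day 0 (s); vectorised.
#' @param lm A [light_model()].
#' @return Irradiance (W/m^2), never negative.
#' @export
surface_light <- function(t, lm) {
  stopifnot(inherits(lm, "light_model"), all(t >= 0))
  t_d <- t %% lm$day_length
  ifelse(t_d <= lm$D_L, lm$I_max * sin(pi * t_d / lm$D_L), 0)
}

#' Irradiance at depth
#'
#' @param z Depth (m, positive downward); vectorised.
#' @param t Time (s), scalar.
#' @param lm A [light_model()].
#' @return Irradiance (W/m^2), non-increasing in `z`.
#' @export
light_at_depth <- function(z, t, lm) {
  stopifnot(all(z >= 0))
  surface_light(t, lm) * exp(-lm$k_I * z)
}
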