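#' Parameters of the light-regulated cell-density model
#'
#' Buoyancy regulation is modelled as a saturating light response of
#' intracellular density: cells ballast (density rises) under saturating
#' light and recover buoyancy (density falls) in darkness, with hard bounds
#' representing the physiological range of gas-vesicle and carbohydrate
#' ballast adjustment.
#'
#' @param c1 Maximum density-increase rate under saturating light
#'   (kg m^-3 s^-1). Default 2.0e-3.
#' @param c2 Density-decrease rate in darkness (kg m^-3 s^-1). Default
#'   6.7e-4.
#' @param K_I Half-saturation irradiance (W/m^2). Default 100.
#' @param rho_min,rho_max Lower/upper cell-density bounds (kg/m^3).
#'   Defaults 985 and 1065.
#' @return An object of class `cell_density_params`.
#' @export
cell_density_params <- function(c1 = 2.0e-3, c2 = 6.7e-4, K_I = 100,
                                rho_min = 985, rho_max = 1065) {
  stopifnot(c1 > 0, c2 > 0, K_I > 0, rho_min < rho_max)
  structure(list(c1 = c1, c2 = c2, K_I = K_I,
                 rho_min = rho_min, rho_max = rho_max),
            class = "cell_density_params")
}

#' @export
print.cell_density_params <- function(x, ...) {
  cat(sprintf(
    "<cell_density_params> c1 = %.3g, c2 = %.3g kg/m3/s, K_I = %g W/m2, rho in [%g, %g] kg/m3\n",
    x$c1, x$c2, x$K_I, x$rho_min, x$rho_max))
  invisible(x)
}

#' Rate of change of cell density under a given irradiance
#'
#' `d rho / dt = c1 * I / (I + K_I) - c2`: equals `-c2` in darkness,
#' `c1/2 - c2` at half-saturation, and approaches `c1 - c2` under saturating
#' light.
#'
#' @param I Irradiance (W/m^2), `>= 0`; vectorised.
#' @param p A [cell_density_params()].
#' @return Density rate (kg m^-3 s^-1).
#' @export
cell_density_rate <- function(I, p) {
  stopifnot(inherits(p, "cell_density_params"))
  if (any(I < 0)) stop("irradiance must be non-negative")
  p$c1 * I / (I + p$K_I) - p$c2
}

#' One forward-Euler update of the cell-density field
#'
#' Advances the per-depth cell density by `dt` under the local irradiance and
#' clips the result to the physiological bounds.
#'
#' @param rho_cell Cell-density field over depth (kg/m^3).
#' @param I Irradiance field over depth (W/m^2), same length.
#' @param dt Time step (s), `> 0`.
#' @param p A [cell_density_params()].
#' @return Updated density field, within `[rho_min, rho_max]`.
#' @export
update_cell_density <- function(rho_cell, I, dt, p) {
  stopifnot(dt > 0, length(rho_cell) == length(I))
  pmin(pmax(rho_cell + dt * cell_density_rate(I, p), p$rho_min), p$rho_max)
}

#' Density of a colony from its cell density
#'
#' Mixes the cell density with ambient water weighted by the fractal
#' cell-volume fraction: `rho_k = rho_w + vfrac(k) * (rho_cell - rho_w)` with
#' `vfrac(k) = k^(1 - 3/Df)`.  A single cell has the cell density; very large
#' tenuous colonies approach the water density.
#'
#' @param k Colony size (cells per colony); vectorised.
#' @param rho_cell Cell density (kg/m^3).
#' @param rho_w Ambient water density (kg/m^3).
#' @param Df Fractal dimension. Default 2.5.
#' @return Colony density (kg/m^3).
#' @export
colony_density <- function(k, rho_cell, rho_w, Df = 2.5) {
  rho_w + cell_volume_fraction(k, Df) * (rho_cell - rho_w)
}

#' Modified Stokes buoyant velocity
#'
#' `w = g d^2 (rho_k / rho_w - 1) / (18 nu)`, signed so positive is sinking
#' (downward) and negative is floating.
#'
#' @param d Equivalent spherical diameter (m); vectorised.
#' @param rho_k Colony density (kg/m^3).
#' @param rho_w Water density (kg/m^3), `> 0`.
#' @param nu Kinematic viscosity (m^2/s), `> 0`.
#' @param g Gravitational acceleration (m/s^2). Default 9.81.
#' @return Velocity (m/s).
#' @export
stokes_velocity <- function(d, rho_k, rho_w, nu, g = 9.81) {
  if (any(d <= 0)) stop("diameter must be positive")
  if (any(nu <= 0) || any(rho_w <= 0)) {
    stop("viscosity and water density must be positive")
  }
  g * d^2 * (rho_k / rho_w - 1) / (18 * nu)
}

#' Buoyant-velocity matrix over size classes and depth
#'
#' Evaluates the modified Stokes velocity for every colony class at every
#' grid node, using the local water density and viscosity from the
#' environment profile and the shared cell-density field.
#'
#' @param rho_cell Cell-density field over depth (kg/m^3).
#' @param env An `env_profile` on the same grid.
#' @param table A [build_colony_table()] result.
#' @param g Gravitational acceleration (m/s^2). Default 9.81.
#' @return Matrix `w[k, z]` (m/s), positive = sinking.
#' @export
velocity_profiles <- function(rho_cell, env, table, g = 9.81) {
  stopifnot(inherits(env, "env_profile"), inherits(table, "colony_table"))
  nz <- length(env$z_nodes)
  if (length(rho_cell) != nz) {
    stop("cell-density field and environment grid lengths differ")
  }
  rho_w <- water_density(env$temp_C)
  nu <- kinematic_viscosity(env$temp_C)
  # w[k, z] = g d_k^2 vfrac_k (rho_cell_z - rho_w_z) / (18 nu_z rho_w_z)
  size_part <- g * table$d_m^2 * table$vfrac / 18
  depth_part <- (rho_cell - rho_w) / (nu * rho_w)
  outer(size_part, depth_part)
}
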