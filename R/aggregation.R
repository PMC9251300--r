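# Boltzmann constant (m^2 kg s^-2 K^-1)
.k_B <- 1.38e-23

#' Brownian-motion collision kernel
#'
#' `beta_Br = 2 T k_B (d_i + d_j)^2 / (3 mu d_i d_j)`: collisions driven by
#' thermal diffusion, largest for very small particles and independent of
#' size for equal-sized pairs.
#'
#' @param T_K Absolute water temperature (K).
#' @param mu Dynamic viscosity (Pa s).
#' @param d_i,d_j Particle diameters (m); vectorised.
#' @return Collision kernel (m^3/s); symmetric in `d_i`, `d_j`.
#' @export
brownian_kernel <- function(T_K, mu, d_i, d_j) {
  stopifnot(all(T_K > 0), all(mu > 0))
  if (any(d_i <= 0) || any(d_j <= 0)) stop("diameters must be positive")
  2 * T_K * .k_B * (d_i + d_j)^2 / (3 * mu * d_i * d_j)
}

#' Turbulent-shear collision kernel
#'
#' `beta_TS = coeff * G * (d_i + d_j)^3` for sub-Kolmogorov particles in
#' turbulent flow; the default coefficient 4/3 applies the classic constant
#' to the summed diameter.  Use `coeff = 1/6` for the radius-convention
#' dialect.
#'
#' @param G Turbulent shear rate (1/s), `>= 0`.
#' @param d_i,d_j Particle diameters (m); vectorised.
#' @param coeff Dimensionless coefficient. Default `4/3`.
#' @return Collision kernel (m^3/s).
#' @export
shear_kernel <- function(G, d_i, d_j, coeff = 4 / 3) {
  if (any(G < 0)) stop("shear rate must be non-negative")
  coeff * G * (d_i + d_j)^3
}

#' Differential-settling collision kernel
#'
#' `beta_DS = coeff * pi * (d_i + d_j)^2 * |w_i - w_j|`: collisions from
#' different-sized aggregates moving at different buoyant velocities; zero
#' for equal velocities.  Use `coeff = 1/4` for the radius-convention
#' dialect.
#'
#' @param d_i,d_j Particle diameters (m); vectorised.
#' @param w_i,w_j Buoyant velocities (m/s).
#' @param coeff Dimensionless coefficient. Default 1.
#' @return Collision kernel (m^3/s).
#' @export
settling_kernel <- function(d_i, d_j, w_i, w_j, coeff = 1) {
  if (any(d_i <= 0) || any(d_j <= 0)) stop("diameters must be positive")
  coeff * pi * (d_i + d_j)^2 * abs(w_i - w_j)
}

#' Collision-kernel and sticking matrices at one depth
#'
#' Evaluates the summed collision kernel (Brownian + turbulent shear +
#' differential settling) and the pairwise sticking matrix for all colony
#' class pairs at the local water conditions.
#'
#' @param table A [build_colony_table()] result.
#' @param temp_C Local water temperature (degC).
#' @param eps Local dissipation rate (m^2/s^3).
#' @param w Buoyant velocities over size classes (m/s); default all zero
#'   (no differential settling contribution).
#' @param shear_coeff Coefficient of the shear kernel. Default `4/3`.
#' @param settling_coeff Coefficient of the settling kernel. Default 1.
#' @param keep_components If `TRUE` (default), retain the per-mechanism
#'   matrices.
#' @return A list of class `kernel_matrices` with symmetric matrices `beta`
#'   (m^3/s) and `alpha` (dimensionless), and optionally `components`
#'   (list `brownian`, `shear`, `settling`).
#' @export
kernel_matrices <- function(table, temp_C, eps,
                            w = rep(0, nrow(table)),
                            shear_coeff = 4 / 3, settling_coeff = 1,
                            keep_components = TRUE) {
  stopifnot(inherits(table, "colony_table"))
  kmax <- nrow(table)
  if (length(w) != kmax) stop("velocity vector length must equal k_max")
  d <- table$d_m
  T_K <- temp_C + 273.15
  mu <- dynamic_viscosity(temp_C)
  nu <- kinematic_viscosity(temp_C)
  G <- shear_rate(eps, nu)
  di <- matrix(d, kmax, kmax)
  dj <- t(di)
  br <- brownian_kernel(T_K, mu, di, dj)
  ts <- shear_kernel(G, di, dj, coeff = shear_coeff)
  wi <- matrix(w, kmax, kmax)
  ds <- settling_kernel(di, dj, wi, t(wi), coeff = settling_coeff)
  ai <- matrix(table$alpha, kmax, kmax)
  alpha <- pair_sticking(ai, t(ai), rule = attr(table, "sticking_rule"))
  out <- list(beta = br + ts + ds, alpha = alpha)
  if (keep_components) {
    out$components <- list(brownian = br, shear = ts, settling = ds)
  }
  structure(out, class = "kernel_matrices")
}

#' @export
print.kernel_matrices <- function(x, ...) {
  cat(sprintf("<kernel_matrices> %d size classes, beta in [%.3g, %.3g] m3/s\n",
              nrow(x$beta), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Truncated Smoluchowski reaction term
#'
#' Net rate of change of each colony-class concentration from pairwise
#' coagulation: `gain(k) = 1/2 * sum over i+j=k of alpha(i,j) beta(i,j) n_i
#' n_j`, `loss(k) = n_k * sum over i = 1..(k_max - k) of alpha(i,k)
#' beta(i,k) n_i`.  The loss sum is truncated so that no pair whose combined
#' size exceeds `k_max` ever reacts; total cell mass `sum(k * rhs)` is
#' conserved exactly.
#'
#' @param n Colony concentrations over size classes (colonies/m^3), `>= 0`.
#' @param km A [kernel_matrices()] result (or any list with symmetric
#'   `beta` and `alpha` matrices of matching size).
#' @return Vector of rates (colonies m^-3 s^-1).
#' @export
smoluchowski_rhs <- function(n, km) {
  kmax <- length(n)
  if (any(n < 0)) stop("concentrations must be non-negative")
  if (nrow(km$beta) != kmax) stop("kernel matrices do not match length of n")
  q <- km$alpha * km$beta
  gain <- numeric(kmax)
  for (k in seq_len(kmax)[-1]) {
    i <- seq_len(k - 1)
    gain[k] <- 0.5 * sum(q[cbind(i, k - i)] * n[i] * n[k - i])
  }
  loss <- numeric(kmax)
  for (k in seq_len(kmax)) {
    imax <- kmax - k
    if (imax >= 1) {
      i <- seq_len(imax)
      loss[k] <- n[k] * sum(q[i, k] * n[i])
    }
  }
  gain - loss
}

#' Analytic constant-kernel coagulation solution
#'
#' Closed-form size spectrum for the untruncated Smoluchowski system with a
#' constant kernel `beta0`, perfect sticking, and a monodisperse initial
#' condition `n_1(0) = N0`:
#' `n_k(t) = N0 * x^(k-1) / (1 + x)^(k+1)` with `x = beta0 N0 t / 2`.
#' Used as an independent oracle for the reaction integrator.
#'
#' @param N0 Initial single-cell concentration (colonies/m^3).
#' @param beta0 Constant kernel (m^3/s).
#' @param t Time (s), `>= 0`; scalar.
#' @param k Colony sizes; vectorised.
#' @return Concentrations (colonies/m^3).
#' @export
constant_kernel_solution <- function(N0, beta0, t, k) {
  stopifnot(N0 > 0, beta0 > 0, t >= 0, all(k >= 1))
  x <- beta0 * N0 * t / 2
  N0 * x^(k - 1) / (1 + x)^(k + 1)
}

#' Dump kernel matrices as delimited text
#'
#' Long format with columns `i`, `j`, `alpha`, `beta` (and per-mechanism
#' columns when components were kept), for inspection.
#'
#' @param km A [kernel_matrices()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_matrices <- function(km, path) {
  kmax <- nrow(km$beta)
  idx <- expand.grid(i = seq_len(kmax), j = seq_len(kmax))
  out <- data.frame(idx, alpha = as.vector(km$alpha),
                    beta = as.vector(km$beta))
  if (!is.null(km$components)) {
    out$brownian <- as.vector(km$components$brownian)
    out$shear <- as.vector(km$components$shear)
    out$settling <- as.vector(km$components$settling)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
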