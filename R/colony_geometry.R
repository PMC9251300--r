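#' Colony porosity for a size class
#'
#' Porosity decreases linearly with colony size (cell count): single cells are
#' fully "porous" (`phi = 1`, i.e. the drag diameter equals the cell diameter)
#' and the largest resolved colony has `phi = phi_min`.
#'
#' @param k Colony size (cells per colony), integer-valued, `1 <= k <= k_max`.
#'   May be a vector.
#' @param k_max Largest resolved colony size (cells per colony).
#' @param phi_max Porosity of a single cell. Default 1.
#' @param phi_min Porosity of a colony of size `k_max`. Default 0.2.
#' @return Porosity (dimensionless), same length as `k`.
#' @examples
#' colony_porosity(1, 101)    # 1
#' colony_porosity(101, 101)  # 0.2
#' @export
colony_porosity <- function(k, k_max, phi_max = 1, phi_min = 0.2) {
  stopifnot(k_max >= 1, phi_min > 0, phi_min <= phi_max, phi_max <= 1)
  if (any(k < 1) || any(k > k_max)) {
    stop("colony size k must lie in [1, k_max]")
  }
  if (k_max == 1) {
    return(rep(phi_max, length(k)))
  }
  phi_max + (phi_min - phi_max) * (k - 1) / (k_max - 1)
}

#' Equivalent spherical diameter of a fractal colony
#'
#' A colony of `k` cells with fractal dimension `Df` has compact linear size
#' `k^(1/Df) * d0`; dividing by the porosity inflates this to the equivalent
#' spherical (drag) diameter used in the collision kernels and Stokes' law.
#'
#' With the defaults (`d0` = 5 um, `Df` = 2.5, porosity falling linearly to
#' 0.2 at `k` = 101) the largest class has a diameter of about 160 um.
#'
#' @param k Colony size (cells per colony); vectorised.
#' @param phi Porosity at that size (see [colony_porosity()]); vectorised.
#' @param d0 Single-cell diameter (m). Default 5e-6.
#' @param Df Fractal dimension, `1 < Df <= 3`. Default 2.5.
#' @param dialect Where the porosity enters: `"divide"` (default) gives
#'   `k^(1/Df) * d0 / phi`; `"power"` puts the porosity under the fractal
#'   exponent, `(k / phi)^(1/Df) * d0`.
#' @return Diameter (m).
#' @examples
#' colony_diameter(101, 0.2)  # ~1.58e-4 m (160 um)
#' @export
colony_diameter <- function(k, phi, d0 = 5e-6, Df = 2.5,
                            dialect = c("divide", "power")) {
  dialect <- match.arg(dialect)
  stopifnot(all(k >= 1), d0 > 0, Df > 1, Df <= 3)
  if (any(phi <= 0)) stop("porosity must be positive")
  switch(dialect,
    divide = k^(1 / Df) * d0 / phi,
    power  = (k / phi)^(1 / Df) * d0
  )
}

#' Ratio of cell volume to compact colony volume
#'
#' For a fractal aggregate of `k` cells the occupied (cell) volume scales as
#' `k` while the compact volume scales as `k^(3/Df)`, so the cell-volume
#' fraction is `k^(1 - 3/Df)`. It equals 1 for a single cell, and is 1 for
#' all sizes when `Df = 3` (space-filling aggregates). Used by the buoyancy
#' module to mix cell density with ambient water density.
#'
#' @param k Colony size (cells per colony); vectorised.
#' @param Df Fractal dimension. Default 2.5.
#' @return Dimensionless fraction in (0, 1].
#' @export
cell_volume_fraction <- function(k, Df = 2.5) {
  stopifnot(all(k >= 1), Df > 0)
  k^(1 - 3 / Df)
}

#' Sticking probability of a colony as a function of its diameter
#'
#' Gaussian in diameter, peaking near the diameters where extracellular
#' polysaccharide (EPS) content of field colonies is largest (100-150 um):
#' `A * exp(-((d - d_c)/s)^2)`. With the defaults a 5-um single cell sticks
#' on about half of its collisions while colonies near 125 um always stick.
#'
#' @param d Equivalent spherical diameter (m); vectorised.
#' @param A Peak sticking probability. Default 0.994.
#' @param d_c Center diameter of the peak (m). Default 1.16e-4.
#' @param s Gaussian width (m). Default 1.34e-4.
#' @return Sticking probability in (0, A].
#' @export
sticking_probability <- function(d, A = 0.994, d_c = 1.16e-4, s = 1.34e-4) {
  stopifnot(all(d > 0), A > 0, A <= 1, s > 0)
  A * exp(-((d - d_c) / s)^2)
}

#' Pairwise sticking probability
#'
#' Combines the per-colony sticking probabilities of a colliding pair.  The
#' default takes the maximum of the two, so the stickier (larger) partner
#' dominates; a product rule is available as a dialect.
#'
#' @param alpha_i,alpha_j Per-colony sticking probabilities in `[0, 1]`;
#'   vectorised (recycled).
#' @param rule `"max"` (default) or `"product"`.
#' @return Pair sticking probability; symmetric in its arguments.
#' @export
pair_sticking <- function(alpha_i, alpha_j, rule = c("max", "product")) {
  rule <- match.arg(rule)
  if (any(alpha_i < 0 | alpha_i > 1) || any(alpha_j < 0 | alpha_j > 1)) {
    stop("sticking probabilities must lie in [0, 1]")
  }
  switch(rule,
    max     = pmax(alpha_i, alpha_j),
    product = alpha_i * alpha_j
  )
}

#' Build the per-size colony class table
#'
#' Tabulates porosity, equivalent spherical diameter, cell-volume fraction and
#' sticking probability for every colony size `k = 1..k_max`.  This table is
#' the geometric backbone shared by the kernel, buoyancy and transport code.
#'
#' @param k_max Largest resolved colony size. Default 101.
#' @param d0 Single-cell diameter (m). Default 5e-6.
#' @param Df Fractal dimension. Default 2.5.
#' @param phi_min Porosity at `k_max`. Default 0.2.
#' @param phi_max Porosity of a single cell. Default 1.
#' @param sticking List with elements `A`, `d_c`, `s` for
#'   [sticking_probability()].
#' @param sticking_rule Pair rule for [pair_sticking()]: `"max"` or
#'   `"product"`.
#' @param diameter_dialect Passed to [colony_diameter()].
#' @return An object of class `colony_table`: a data frame with columns `k`,
#'   `phi`, `d_m`, `vfrac`, `alpha` and attributes recording the parameters.
#' @examples
#' tab <- build_colony_table()
#' tab$d_m[101] * 1e6  # ~158 um
#' @export
build_colony_table <- function(k_max = 101, d0 = 5e-6, Df = 2.5,
                               phi_min = 0.2, phi_max = 1,
                               sticking = list(A = 0.994, d_c = 1.16e-4,
                                               s = 1.34e-4),
                               sticking_rule = c("max", "product"),
                               diameter_dialect = c("divide", "power")) {
  sticking_rule <- match.arg(sticking_rule)
  diameter_dialect <- match.arg(diameter_dialect)
  stopifnot(k_max >= 1)
  k <- seq_len(k_max)
  phi <- colony_porosity(k, k_max, phi_max = phi_max, phi_min = phi_min)
  d <- colony_diameter(k, phi, d0 = d0, Df = Df, dialect = diameter_dialect)
  vfrac <- cell_volume_fraction(k, Df = Df)
  alpha <- sticking_probability(d, A = sticking$A, d_c = sticking$d_c,
                                s = sticking$s)
  tab <- data.frame(k = k, phi = phi, d_m = d, vfrac = vfrac, alpha = alpha)
  if (k_max > 1 && any(diff(d) <= 0)) {
    stop("colony diameters are not strictly increasing; check d0/Df/porosity")
  }
  if (any(alpha <= 0) || any(alpha > 1)) {
    stop("sticking probabilities fall outside (0, 1]")
  }
  structure(tab,
            class = c("colony_table", "data.frame"),
            k_max = k_max, d0 = d0, Df = Df,
            phi_min = phi_min, phi_max = phi_max,
            sticking = sticking, sticking_rule = sticking_rule,
            diameter_dialect = diameter_dialect)
}

#' @export
print.colony_table <- function(x, ...) {
  cat(sprintf(
    "<colony_table> k_max = %d, d0 = %.3g um, Df = %.3g, phi in [%.3g, %.3g]\n",
    attr(x, "k_max"), attr(x, "d0") * 1e6, attr(x, "Df"),
    attr(x, "phi_min"), attr(x, "phi_max")))
  cat(sprintf("  diameters %.3g-%.3g um; alpha in [%.3g, %.3g] (%s pair rule)\n",
              min(x$d_m) * 1e6, max(x$d_m) * 1e6,
              min(x$alpha), max(x$alpha), attr(x, "sticking_rule")))
  invisible(x)
}

#' Write a colony class table to delimited text
#'
#' Columns: `k`, `d_m`, `phi`, `vfrac`, `alpha` (comma-separated).
#'
#' @param table A [build_colony_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(table, path) {
  stopifnot(inherits(table, "colony_table"))
  utils::write.csv(table[c("k", "d_m", "phi", "vfrac", "alpha")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
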