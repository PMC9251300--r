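#' Total cell concentration over depth
#'
#' `C(z) = sum over k of k * n_k(z)` (cells/m^3): colony concentrations
#' weighted by the number of cells they contain.
#'
#' @param n Concentration matrix `n[k, z]` (colonies/m^3).
#' @return Vector over depth (cells/m^3).
#' @export
total_concentration <- function(n) {
  if (any(n < 0)) stop("concentrations must be non-negative")
  colSums(n * seq_len(nrow(n)))
}

#' Column-integrated cell count per size class
#'
#' `N_k = sum over z of k * n_k(z) * dz` (cells/m^2).  Because concentration
#' is continuous, `N_k` may be smaller than `k` (less than one colony in the
#' column) without error.
#'
#' @param n Concentration matrix `n[k, z]` (colonies/m^3).
#' @param dz Grid cell width (m).
#' @param k Size class (or vector of classes); `NULL` (default) returns all
#'   classes.
#' @return Cell counts (cells/m^2).
#' @export
cell_count <- function(n, dz, k = NULL) {
  K <- nrow(n)
  Nk <- seq_len(K) * .rowSums(n, K, ncol(n)) * dz
  if (is.null(k)) Nk else Nk[k]
}

#' Column-integrated total cell mass
#'
#' `M = sum over k, z of k * n_k(z) * dz` (cells/m^2); conserved by the
#' solver (no growth, no loss through the boundaries).
#'
#' @inheritParams cell_count
#' @return Total cells per unit lake area (cells/m^2).
#' @export
mass_audit <- function(n, dz) {
  sum(cell_count(n, dz))
}

#' @export
print.diagnostics_series <- function(x, ...) {
  rel <- abs(x$mass[length(x$mass)] - x$mass[1]) / x$mass[1]
  cat(sprintf(
    "<diagnostics_series> %d outputs over %.3g d, %d size classes\n",
    length(x$times), max(x$times) / 86400, x$k_max))
  cat(sprintf("  mass %.4g cells/m2 (rel. drift %.2e), %d concentration snapshots\n",
              x$mass[1], rel, length(x$C_snapshots$times)))
  invisible(x)
}

#' Time of first appearance of a colony size
#'
#' The appearance time tau_k is the earliest time at which the column cell
#' count `N_k(t)` reaches the threshold (1 cell/m^2 by default), linearly
#' interpolated between the bracketing recorded outputs.
#'
#' @param series A `diagnostics_series` (from [run_simulation()]).
#' @param k Size class.
#' @param threshold Appearance threshold (cells/m^2). Default 1.
#' @return Appearance time (s), or `NA` if never attained during the run.
#' @export
appearance_time <- function(series, k, threshold = 1) {
  stopifnot(inherits(series, "diagnostics_series"), threshold > 0)
  Nk <- series$N[k, ]
  t <- series$times
  hit <- which(Nk >= threshold)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  i <- hit[1]
  if (i == 1) {
    return(t[1])
  }
  # linear interpolation between the bracketing outputs
  t[i - 1] + (threshold - Nk[i - 1]) * (t[i] - t[i - 1]) / (Nk[i] - Nk[i - 1])
}

#' Power-law fit of appearance time against initial concentration
#'
#' Ordinary least squares of `log10(tau)` on `log10(n0)`:
#' `tau = prefactor * n0^slope`.
#'
#' @param n0 Initial mixed-layer concentrations (cells/m^3), all positive.
#' @param tau Appearance times (s or d, any consistent unit), all positive.
#' @return List with `slope`, `intercept` (log10 prefactor), `prefactor`,
#'   and the fitted `lm` object.
#' @export
powerlaw_fit <- function(n0, tau) {
  if (length(n0) != length(tau) || length(n0) < 2) {
    stop("need at least two (n0, tau) points")
  }
  if (any(n0 <= 0) || any(tau <= 0) || any(is.na(tau))) {
    stop("all n0 and tau values must be positive and non-missing")
  }
  fit <- stats::lm(log10(tau) ~ log10(n0))
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       prefactor = 10^unname(cf[1]), fit = fit)
}

#' Concentration sweep of large-colony appearance times
#'
#' Reruns the scenario for a list of initial mixed-layer concentrations,
#' records the appearance time of the target size class in each run, and
#' fits the log-log power law relating appearance time to initial
#' concentration.
#'
#' @param n0_values Initial single-cell concentrations (cells/m^3).
#' @param cfg Template [numerical_config()]; `n0` is overridden per run.
#' @param table A [build_colony_table()] result.
#' @param k Target size class. Default `k_max`.
#' @param threshold Appearance threshold (cells/m^2). Default 1.
#' @param tau_units `"days"` (default) or `"seconds"` for the returned
#'   times.
#' @param ... Further arguments passed to [run_simulation()].
#' @return List of class `sweep_result`: data frame `points`
#'   (`n0`, `tau`, `reached`), the power-law `fit` over the reached points
#'   (or `NULL` if fewer than two), and the inputs.
#' @export
concentration_sweep <- function(n0_values, cfg,
                                table = build_colony_table(),
                                k = nrow(table), threshold = 1,
                                tau_units = c("days", "seconds"), ...) {
  tau_units <- match.arg(tau_units)
  stopifnot(all(n0_values > 0))
  tau <- rep(NA_real_, length(n0_values))
  for (i in seq_along(n0_values)) {
    cfg_i <- cfg
    cfg_i$n0 <- n0_values[i]
    sim <- run_simulation(cfg_i, table, ...)
    tau[i] <- appearance_time(sim$diagnostics, k, threshold)
  }
  if (tau_units == "days") tau <- tau / 86400
  reached <- !is.na(tau)
  fit <- if (sum(reached) >= 2) {
    powerlaw_fit(n0_values[reached], tau[reached])
  }
  structure(list(points = data.frame(n0 = n0_values, tau = tau,
                                     reached = reached),
                 fit = fit, k = k, threshold = threshold,
                 tau_units = tau_units),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> tau_%d over %d concentrations (%d reached)\n",
              x$k, nrow(x$points), sum(x$points$reached)))
  if (!is.null(x$fit)) {
    cat(sprintf("  tau = %.3g * n0^%.3g (%s)\n",
                x$fit$prefactor, x$fit$slope, x$tau_units))
  }
  invisible(x)
}

#' Write diagnostics to delimited text
#'
#' Long format `time_s, k, N_k` (cells/m^2), one row per recorded output and
#' size class.
#'
#' @param series A `diagnostics_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(series, path) {
  stopifnot(inherits(series, "diagnostics_series"))
  out <- data.frame(time_s = rep(series$times, each = series$k_max),
                    k = rep(seq_len(series$k_max), length(series$times)),
                    N_k = as.vector(series$N))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write total-concentration snapshots to delimited text
#'
#' Long format `time_s, depth_m, C_cells_m3`.
#'
#' @param series A `diagnostics_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(series, path) {
  stopifnot(inherits(series, "diagnostics_series"))
  sn <- series$C_snapshots
  out <- data.frame(time_s = rep(sn$times, each = length(series$z_nodes)),
                    depth_m = rep(series$z_nodes, length(sn$times)),
                    C_cells_m3 = as.vector(sn$C))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
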