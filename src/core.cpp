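#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// q(i,j) at one depth: static (sticking * (Brownian + shear)) part plus the
// differential-settling part rebuilt from the current velocity field.
static inline double qval(const double* abz, const double* as,
                          const double* wz, int K, int i, int j) {
  return abz[i + (size_t)K * j] + as[i + (size_t)K * j] * std::fabs(wz[i] - wz[j]);
}

// Truncated Smoluchowski gain-loss for one water-column cell.  Writes the
// net rate into rhs and returns the largest per-class loss-rate coefficient
// (1/s), used by the positivity guard.  Pairs whose combined size exceeds K
// never react, so sum(k * rhs) telescopes to zero exactly.
static double react_col(const double* nz_, const double* abz, const double* as,
                        const double* wz, int K, double* rhs) {
  for (int k = 0; k < K; ++k) rhs[k] = 0.0;
  for (int is = 1; is < K; ++is) {        // gain into size is+1
    double g = 0.0;
    for (int ia = 0; ia <= is - 1; ++ia) {
      int ib = is - 1 - ia;               // sizes (ia+1) + (ib+1) = is+1
      g += qval(abz, as, wz, K, ia, ib) * nz_[ia] * nz_[ib];
    }
    rhs[is] += 0.5 * g;
  }
  double lmax = 0.0;
  for (int is = 0; is < K; ++is) {        // loss of size is+1
    int amax = K - (is + 1);              // largest partner size allowed
    double L = 0.0;
    for (int ia = 0; ia < amax; ++ia)
      L += qval(abz, as, wz, K, ia, is) * nz_[ia];
    rhs[is] -= nz_[is] * L;
    if (L > lmax) lmax = L;
  }
  return lmax;
}

// [[Rcpp::export]]
NumericMatrix cpp_reaction_rhs(const NumericMatrix& n,
                               const NumericVector& ab_static,
                               const NumericMatrix& asett,
                               const NumericMatrix& w) {
  const int K = n.nrow(), nz = n.ncol();
  NumericMatrix rhs(K, nz);
  const double* ab = ab_static.begin();
  const double* as = asett.begin();
  for (int z = 0; z < nz; ++z) {
    react_col(&n(0, z), ab + (size_t)K * K * z, as, &w(0, z), K, &rhs(0, z));
  }
  return rhs;
}

// One explicit forward-in-time step of the coupled finite-volume
// advection-dispersion + Smoluchowski update.  Fluxes live at cell faces
// (positive downward), concentrations at cell nodes; the surface and bottom
// faces carry exactly zero flux.  Transport and reaction are combined in a
// single explicit update evaluated at the current time level; if the
// reaction loss fraction dt * L exceeds `guard`, the reaction alone is
// sub-stepped internally to preserve positivity.
// [[Rcpp::export]]
List cpp_step(const NumericMatrix& n, const NumericVector& ab_static,
              const NumericMatrix& asett, const NumericMatrix& w,
              const NumericVector& Dface, double dz, double dt,
              double guard, int max_substeps) {
  const int K = n.nrow(), nz = n.ncol();
  if (Dface.size() != nz + 1) stop("Dface must have length nz + 1");
  NumericMatrix out(K, nz);
  std::vector<double> flux(nz + 1);
  // transport increment (stored in out as n + dt * transport)
  for (int k = 0; k < K; ++k) {
    flux[0] = 0.0;
    flux[nz] = 0.0;
    for (int f = 1; f < nz; ++f) {
      double wf = 0.5 * (w(k, f - 1) + w(k, f));
      double nstar = (wf >= 0.0) ? n(k, f - 1) : n(k, f);
      flux[f] = -Dface[f] * (n(k, f) - n(k, f - 1)) / dz + wf * nstar;
    }
    for (int i = 0; i < nz; ++i)
      out(k, i) = n(k, i) + dt * (flux[i] - flux[i + 1]) / dz;
  }
  // reaction at time level m, with positivity guard
  const double* ab = ab_static.begin();
  const double* as = asett.begin();
  NumericMatrix rhs(K, nz);
  double lmax = 0.0;
  for (int z = 0; z < nz; ++z) {
    double l = react_col(&n(0, z), ab + (size_t)K * K * z, as, &w(0, z), K,
                         &rhs(0, z));
    if (l > lmax) lmax = l;
  }
  int nsub = 1;
  if (dt * lmax <= guard) {
    for (int z = 0; z < nz; ++z)
      for (int k = 0; k < K; ++k) out(k, z) += dt * rhs(k, z);
  } else {
    nsub = (int)std::ceil(dt * lmax / guard);
    if (nsub > max_substeps)
      stop("reaction requires %d sub-steps (> max_substeps = %d); "
           "reduce dt or concentrations", nsub, max_substeps);
    double dts = dt / nsub;
    std::vector<double> r(K);
    for (int s = 0; s < nsub; ++s) {
      for (int z = 0; z < nz; ++z) {
        react_col(&out(0, z), ab + (size_t)K * K * z, as, &w(0, z), K,
                  r.data());
        for (int k = 0; k < K; ++k) out(k, z) += dts * r[k];
      }
    }
  }
  return List::create(_["n"] = out, _["substeps"] = nsub);
}
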