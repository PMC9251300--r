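# cyanoagg

Coupled aggregation and vertical transport of colony-forming cyanobacteria
in a stratified water column.

## The problem

Surface blooms of *Microcystis aeruginosa* are built from large colonies,
yet populations typically start a season as single cells. Two traits drive
the transition and the vertical structure that precedes a bloom: colonies
grow by **physical collision and adhesion**, and they **migrate
vertically** by light-regulated buoyancy while turbulence disperses them.
`cyanoagg` implements a size-resolved model that couples both processes,
for researchers studying harmful-algal-bloom initiation, vertical
heterogeneity of cyanobacteria, or coagulation dynamics in lakes.

## The model

For each colony size class `k = 1..k_max` (cells per colony), the
concentration `n_k(z, t)` (colonies/m³) obeys a 1D
advection–dispersion–reaction equation:

    dn_k/dt = d/dz( D_Z dn_k/dz ) - d/dz( w_k n_k )
            + 1/2 Σ_{i+j=k} α(i,j) β(i,j,z) n_i n_j
            - Σ_{i=1}^{k_max-k} α(i,k) β(i,k,z) n_i n_k

with no-flux boundaries (cells cannot leave the column) and a truncated
Smoluchowski reaction term that conserves total cell mass exactly.

* **Collision kernel** `β = β_Brownian + β_shear + β_settling`, evaluated
  from local temperature, viscosity, dissipation rate
  (`G = sqrt(ε/ν)`), and per-class buoyant velocities.
* **Colony geometry** is fractal (`Df = 2.5`): drag diameter
  `d_k = k^(1/Df) d0 / φ(k)` with porosity `φ` falling linearly from 1 to
  0.2, giving `d_101 ≈ 160 µm` from 5 µm cells.
* **Sticking probability** is a Gaussian in diameter peaking near 116 µm
  (EPS-rich sizes); pairs use `α(i,j) = max(α_i, α_j)`.
* **Buoyancy**: a light-driven cell-density field (ballasting under light,
  recovery in darkness, clipped to [985, 1065] kg/m³) sets colony density
  through the fractal cell-volume fraction `k^(1-3/Df)`, and a modified
  Stokes law `w_k = g d_k² (ρ_k/ρ_W - 1) / (18ν)` gives sinking (positive)
  or floating (negative) speeds, spanning ~1e-6 m/s for single cells to
  ~1e-3 m/s for the largest classes.
* **Numerics**: explicit forward-in-time finite-volume upwind scheme
  (defaults 0.2 m, 10 s over 10 m), stability-checked, with automatic
  sub-stepping of the reaction when concentrations are high. The hot loop
  is compiled (Rcpp); a pure-R reference path is kept for verification.

Water-column forcing comes from delimited-text profiles
(`depth_m,temp_C,Dz_m2s,eps_m2s3`) or a built-in synthetic generator with
high-wind (`ε_max = 4e-4 m²/s³`) and low-wind (`ε_max = 3e-7 m²/s³`)
regimes and stepwise wind schedules.

## Worked example

```r
library(cyanoagg)

tab <- build_colony_table(k_max = 25)
tab
#> <colony_table> k_max = 25, d0 = 5 um, Df = 2.5, phi in [0.2, 1]
#>   diameters 5-90.6 um; alpha in [0.5, 0.959] (max pair rule)

cfg <- numerical_config(dz = 0.5, dt = 30, t_end = 14 * 86400, n0 = 1e8)
stability_check(cfg, synthetic_profile(config_nodes(cfg), "high_wind"), tab)
#> <stability_report> diffusion number 0.12 (ok), Courant 0.0108 (ok)
#>   max |w| = 0.000179 m/s, max D = 0.001 m2/s, reaction loss fraction/step ~ 12.1

sim <- run_simulation(cfg, tab)   # synthetic high-wind column
sim
#> <hab_simulation> 14 days, 25 size classes, 20 cells
#>   mass balance rel. error 1.99e-16; largest class with N_k >= 1: 25

appearance_time(sim$diagnostics, 25) / 86400
#> [1] 4.994823

sw <- concentration_sweep(c(1e8, 2e8, 4e8), cfg, tab)
sw
#> <sweep_result> tau_25 over 3 concentrations (3 reached)
#>   tau = 8.99e+10 * n0^-1.28 (days)
```

Reading the output: the stability report confirms the explicit scheme is
safely inside its diffusion and Courant bounds (the reaction estimate
above 1 signals the solver will sub-step the reaction at this
concentration). Over two weeks of constant high wind at 1e8 cells/m³, the
initial single-cell population cascades all the way to the largest
resolved class, crossing the one-cell-per-column appearance threshold
(`N_25 = 1 cells/m²`) after about 5 days, with total cell mass conserved
to machine precision. Halving/doubling the initial concentration shifts
the appearance time with a log–log slope near −1.3: aggregation speed is
roughly inversely proportional to algal concentration, which is why late-
season wind events (high standing stock) matter far more than early ones.

A thin command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cyanoagg", package = "cyanoagg"))')
Rscript $CLI table --out out/            # colony class table
Rscript $CLI check                       # stability report
Rscript $CLI run --regime daily --days 28 --out out/
Rscript $CLI sweep --n0 1e8,2e8,4e8 --out out/
```

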