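---
title: "Coupled colony aggregation and vertical transport in a stratified water column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled colony aggregation and vertical transport in a stratified water column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoagg)
```

## The model

`cyanoagg` simulates how a population of buoyant, colony-forming
cyanobacteria (the archetype is *Microcystis aeruginosa*) evolves in a
stratified lake water column when two processes act together:

1. **Coagulation.** Colonies of `k` cells collide and stick, following the
   discrete Smoluchowski population balance. For the concentration
   `n_k(z, t)` of colonies containing `k` cells (colonies/m³), the reaction
   term is

   ```
   dn_k/dt = 1/2 * sum_{i+j=k} alpha(i,j) beta(i,j,z) n_i n_j
           -       sum_{i=1}^{k_max - k} alpha(i,k) beta(i,k,z) n_i n_k
   ```

   The upper limit `k_max - k` on the loss sum truncates the system: pairs
   whose combined size would exceed `k_max` never react, so total cell mass
   `sum_k k n_k` is conserved exactly and no mass is lost to an unresolved
   "gel" class. Fragmentation is deliberately absent: below the largest
   stable colony size, disaggregation of *Microcystis* colonies is
   negligible under field turbulence, which is precisely why the size
   domain is capped.

2. **Vertical transport.** Each size class is advected by its own buoyant
   velocity `w_k(z, t)` and dispersed by a depth-dependent coefficient
   `D_Z(z)`, giving one advection–dispersion–reaction equation per class
   with no-flux boundaries at the surface and the bed (cells cannot leave
   the column).

### Collision kernels

The collision kernel is the sum of three mechanisms, each a standard
coagulation closure evaluated with the local water properties:

* Brownian motion: `2 T k_B (d_i + d_j)² / (3 mu d_i d_j)` — relevant only
  for the smallest colonies;
* turbulent shear: `(4/3) G (d_i + d_j)³` with shear rate
  `G = sqrt(eps / nu)` — the dominant mechanism whenever the wind stirs the
  mixed layer;
* differential settling: `pi (d_i + d_j)² |w_i - w_j|` — relevant for pairs
  of very different size and ballast.

Two conventions circulate for the shear and settling coefficients,
depending on whether the classic constants are applied to summed radii or
summed diameters. The package defaults to the diameter form with
coefficients 4/3 and pi, which is the reading consistent with the reported
kernel ceiling of about 1e-9 m³/s for the largest pair under high-wind
surface conditions; `kernel_opts = list(shear_coeff = 1/6, settling_coeff
= 1/4)` switches to the radius convention.

### Fractal colony geometry

Colonies grown by collision are fractal with dimension `Df = 2.5`. A colony
of `k` cells has equivalent spherical (drag) diameter

```
d_k = k^(1/Df) * d0 / phi(k)
```

where `d0 = 5 µm` is the single-cell diameter and the porosity `phi`
decreases linearly in `k` from 1 (single cell) to 0.2 (largest class).
With `k_max = 101` this puts the largest class near 160 µm and the class
`k = 95` near 125 µm. The placement of the porosity (dividing the whole
expression rather than sitting under the fractal exponent) was chosen
because it reproduces both of those anchor diameters simultaneously; the
alternative reading is available via `colony_diameter(..., dialect =
"power")`. Note that extrapolating the adopted relation beyond `k_max`
does not reproduce the often-quoted association of 220 µm with `k ≈ 580`;
the relation is only used inside the resolved size domain, where it is
anchored at both ends.

Sticking probability rides on extracellular polysaccharide (EPS) content,
which in field colonies peaks at diameters of 100–150 µm. It is modelled as
a Gaussian in diameter, `alpha(d) = 0.994 exp(-((d - 116 µm)/134 µm)²)`:
single cells stick on about half of their collisions, classes near 125 µm
essentially always. For a colliding pair the package takes
`alpha(i,j) = max(alpha_i, alpha_j)` — the stickier, larger partner
dominates, which is what makes large colonies accumulate mass faster than
small ones. A multiplicative rule is available as a dialect
(`sticking_rule = "product"`) but is not the default because it would make
mixed pairs *less* sticky than their large partner.

### Light-regulated buoyancy

Buoyancy regulation follows the classic ballast picture: under bright
light, cells photosynthesize, accumulate carbohydrate ballast and densify;
in darkness they consume it and regain buoyancy through their gas
vesicles. The package models the shared cell-density field `rho_cell(z)`
with a saturating light response,

```
d rho_cell / dt = c1 * I / (I + K_I) - c2,   clipped to [rho_min, rho_max]
```

with defaults `c1 = 2.0e-3` and `c2 = 6.7e-4` kg m⁻³ s⁻¹, half-saturation
`K_I = 100 W/m²`, and bounds `[985, 1065] kg/m³`. The exact functional form
used by earlier *Microcystis* motility models is not uniquely pinned down
in the sources this package follows, so this reconstruction is the
Kromkamp–Walsby-type formulation those models derive from; what the
package treats as authoritative is the *velocity* envelope it produces
(next paragraph), not the constants. All of them are configurable through
`cell_density_params()`.

Colony density mixes cell density with ambient water weighted by the
fractal cell-volume fraction `vfrac(k) = k^(1 - 3/Df)`, and the buoyant
velocity is the modified Stokes law

```
w_k = g d_k² (rho_k / rho_W - 1) / (18 nu),    positive = sinking.
```

The drag diameter here is the porosity-inflated `d_k`, while the density
mixing uses the compact fractal volume. This split is deliberate: it is the
only combination we found that simultaneously yields single-cell speeds
near 1e-6 m/s, large-colony speeds inside the reported band (−1e-4
floating to 1e-3 m/s sinking), and the 160 µm anchor diameter. Folding the
porosity into the density mixing as well collapses the velocities by about
two orders of magnitude. The EPS contribution to colony density is not
modelled separately (no density values are available for it); it is folded
into the cell-density bounds.

The cell-density field is shared by all size classes and is local to each
depth — it is not advected with the colonies. Per-class density fields
would require a transport equation per class for the ballast state, which
none of the source models carry; this is a documented extension point.

### Water-column forcing

Temperature, dispersion `D_Z(z)` and dissipation `eps(z)` come either from
delimited text profiles (`read_profile_table()`, columns `depth_m, temp_C,
Dz_m2s, eps_m2s3`) or from the synthetic generator
`synthetic_profile()`. The generator emulates a summer dimictic column
with a tanh two-layer temperature profile and mixed-layer plateaus for
`D_Z` and `eps`:

| parameter | high wind | low wind | basis |
|---|---|---|---|
| `eps_max` (m²/s³) | 4e-4 | 3e-7 | field maxima at ~8 and ~2 m/s winds |
| `D_max` (m²/s) | 1e-3 | 1e-5 | within the 1e-6–1e-2 lake range; keeps the 0.2 m / 10 s scheme diffusively stable |
| `D_background` (m²/s) | 1e-6 | 1e-6 | molecular floor |
| `h_ML` (m) | 3 | 3 | free parameter of a 10 m column |
| `T_epi`, `T_hypo` (°C) | 25, 12 | 25, 12 | late-summer temperate lake |

The synthetic profiles match the measured regime **maxima** by
construction but not the measured profile **shapes** — the archived field
profiles are not required by the package. Consequently, absolute
appearance times computed with the synthetic stand-ins are slower than the
field-profile base case (the tanh roll-off lets the initial mixed-layer
patch dilute downward), and the package's tests therefore assert the
*relative* contrasts between scenarios rather than absolute day counts.

Surface irradiance is a half-sine over a 16 h photoperiod with peak
800 W/m², zero during the remaining 8 h of the diel cycle (the sine is
truncated rather than allowed to go negative), attenuated with depth as
`exp(-1.3 z)`.

Wind scenarios are stepwise schedules (`scenario_schedule()`): constant
high wind, constant low wind, or 50/50 alternation on a daily or hourly
period.

## Numerics

The solver is an explicit forward-in-time finite-volume scheme on a
uniform grid: concentrations at cell centers `(i - 1/2) dz`, fluxes at
faces, advection upwinded (the face takes the upstream node, with the
`w >= 0` tie going to the node above), diffusion centered, and the surface
and bottom face fluxes hard-coded to zero. Face values of `D` and `w` are
arithmetic means of the adjacent nodes. Transport and reaction are
combined in a single explicit update evaluated at the current time level;
within a step the order is environment → light → cell density → velocities
→ fluxes + reaction.

Defaults are `dz = 0.2 m`, `dt = 10 s`, `z_max = 10 m`
(`numerical_config()`), with a `"fine"` preset of 0.1 m / 5 s. Before a
run, `stability_check()` verifies the diffusion number `max(D) dt / dz²
<= 0.5` and the Courant number `max|w| dt / dz <= 1` (velocities taken at
the ballast bounds) and refuses to start otherwise. Under those bounds the
combined update is positivity-preserving, except possibly for the
quadratic reaction loss: if the per-step loss fraction `dt * max_k
(loss_k / n_k)` would exceed 0.1, the reaction alone is sub-stepped
internally (transport is still applied once). This matters at sweep
concentrations of 1e8–1e9 cells/m³, where the nominal time step would
otherwise drive concentrations negative. Mass conservation is exact by
construction (telescoping interior fluxes, zero boundary fluxes, and a
reaction term whose weighted sum telescopes); runs audit it at every
output and error on non-finite or negative states.

Degenerate inputs are handled explicitly: a single-class system
(`k_max = 1`) has no reactions at all; `t_end = 0` returns the initial
condition; a whole-column mixed layer gives a uniform start; appearance
times that never occur return `NA` rather than an error.

The hot loop (kernel contraction over all class pairs at every depth and
step) is implemented in C++ via Rcpp. A pure-R reference path built from
the exported `face_values()`, `advective_diffusive_flux()` and
`smoluchowski_rhs()` operations is kept alongside
(`use_compiled = FALSE`), and the test suite holds the two paths and an
independent brute-force double-loop oracle to mutual agreement.

### Numerical dispersion

First-order upwinding is numerically dispersive, and at full resolution
the appearance time of the largest class is known to shift by order 20%
under grid refinement (a coarse grid smears sharp migrating fronts and
accelerates apparent aggregation). At the reduced problem sizes used in
this package's test suite the coarse/fine discrepancy collapses to about
1% and its sign is not stable, so the tests assert only that refinement
shifts appearance times by less than 20%; the sign of the shift is a
full-resolution phenomenon that a desk-scale suite cannot resolve.

## What the tests do and do not show

The test suite runs at deliberately reduced problem sizes so the whole
suite completes in about a minute: `k_max = 25` size classes, `dz = 0.5 m`,
`dt = 30 s` for week-long column runs, and a well-mixed 1-m column with
`k_max = 101` for the scenario contrasts. These sizes were chosen as the
smallest systems in which each asserted property is well separated from
its tolerance.

Verified against independent oracles:

* the reaction integrator against the analytic constant-kernel spectrum
  `n_k = N0 x^(k-1) / (1+x)^(k+1)`, `x = beta0 N0 t / 2` (1% for
  `k <= 10` at early times);
* the combined step against literal double-loop re-implementations of the
  upwind flux update and the Smoluchowski gain/loss sums;
* pure diffusion of a cosine mode against the analytic decay rate, with
  the error shrinking under refinement;
* mass conservation to 1e-10 over multi-day runs, positivity, and
  byte-identical reruns.

Scenario-level assertions use the synthetic forcing and therefore carry
its caveats: they demonstrate that high wind aggregates dramatically
faster than low wind, that 50/50 intermittent wind roughly halves the
aggregation speed, and that appearance times scale roughly inversely with
initial concentration (fast at 1e8 cells/m³, beyond two weeks at 1e7) —
but they do not validate absolute appearance times against field
conditions, which depend on the true profile shapes. Equally, passing
tests say nothing about processes the model excludes by design:
fragmentation above `k_max`, cell growth and nutrient dynamics,
temperature-gated buoyancy recovery, horizontal transport, or toxin
dynamics.

## A worked example

```{r example, eval = FALSE}
library(cyanoagg)

tab <- build_colony_table()            # k_max = 101, d0 = 5 um, Df = 2.5
cfg <- numerical_config(dz = 0.5, dt = 30, t_end = 14 * 86400, n0 = 1e8)
sim <- run_simulation(cfg, tab)        # synthetic high-wind column

appearance_time(sim$diagnostics, 101) / 86400   # days to the largest class
print(sim)                                      # mass balance audit

# concentration sweep and power-law fit
sw <- concentration_sweep(c(1e8, 2e8, 4e8), cfg, tab)
sw$fit$slope
```

The command-line wrapper installed at
`system.file("cli", "cyanoagg", package = "cyanoagg")` exposes the same
functionality as `table`, `check`, `run` and `sweep` subcommands.
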