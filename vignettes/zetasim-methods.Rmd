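---
title: "Methods: the model, its scaling, and the numerics behind zetasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the model, its scaling, and the numerics behind zetasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`zetasim` simulates competition between microbial genotypes on a
two-dimensional lattice. Each genotype field $B_i(x, y, t)$ grows with
Monod kinetics on a single shared resource $R(x, y, t)$, and both spread
by diffusion:

$$\partial_t B_i = D_B \nabla^2 B_i + \mu_i B_i \frac{R}{R+k}, \qquad
\partial_t R = D_R \nabla^2 R - \sum_i \lambda\,\mu_i B_i \frac{R}{R+k}.$$

Assumptions worth making explicit: a single limiting resource; no cell
death, maintenance metabolism, or active motility (cells move only by
passive diffusion, a thousand times more slowly than the resource); yield
is constant ($\lambda$ resources per cell); colonies are two-dimensional
fields, with no vertical structure.

## Parameters

| parameter | units | default | why |
|---|---|---|---|
| `D_R` | cm²/h | 1.8e-2 (= 5e-6 cm²/s) | typical of a small sugar diffusing in water or ~1% agar |
| `D_B` | cm²/h | 1.8e-5 | cells diffuse ~1000× slower than their resource |
| `mu` | 1/h | swept 0.01–0.4; mutant = 1.1 × ancestor | spans slow to fast growers; a 10% benefit is a strong but realistic beneficial mutation |
| `k` | resource units | 1 | half-maximal growth at one cell-equivalent of resource; 50 available as a robustness setting |
| `lam` | resources/cell | 1 | one resource unit builds one cell, so biomass and resource share a scale |
| `R0` | per box | 100 | enough for ~11 doublings per batch from 49 founders on a 101×101 lattice |

Constructors accept a `units` tag (`cm2_per_h` / `cm2_per_s`) and convert
on ingest, to prevent 3600-fold unit mistakes. Growth rates are stored
fastest-first, so $\mu_1$ (the rate the scaling divides by) is always
`mu[1]`.

## Scaling and $\zeta$

Dividing resource by $k$, biomass by $k/\lambda$, time by $1/\mu_1$, and
space by $x_c = \sqrt{D_R/\mu_1}$ leaves a model with only three knobs:
the relative diffusion constant $D_c = D_B/D_R$, relative rates
$\mu_{i,\mathrm{rel}} = \mu_i/\mu_1$, and the scaled initial resource
$R_0/k$. The spatial statistic that organizes every experiment is the
scaled mean intercolony distance
$\zeta = \overline{IC}/\sqrt{D_R/\mu_1}$, where $\overline{IC}$ averages
each colony's minimum center-to-center distance to another colony
(minimum-image distances on toroidal domains). Because only the ratio
matters, doubling $\overline{IC}$ is exactly equivalent to quadrupling
$\mu_1$, an identity `compute_zeta` satisfies to machine precision and the
tests assert.

Scaled-model sweeps have no explicit $\mu_1$; the natural length scale is
varied through the scaled box width $\hat h = dx\sqrt{\mu_1/D_R}$ at fixed
box count, which is how `localization_sweep` and `selection_assay` sweep
$\zeta$.

# Numerics

**Operator splitting.** Each step applies per-box Monod growth over `dt`,
then one explicit diffusion update of every field (growth-then-diffusion,
in that order). The time step is the diffusion stability rule taken as an
equality, `dt = 0.1 dx²/D_max`, with `D_max` the largest diffusion
constant in play (the resource's); a user-supplied `dt` above the bound is
rejected, never silently sub-stepped.

**Growth substep.** Within a box the reaction system collapses exactly to
one scalar unknown: with $G(t) = \int_0^t R/(R+k)\,ds$,
$B_i(t) = B_i(0)e^{\mu_i G}$ and
$R(t) = R(0) - \lambda \sum_i B_i(0)(e^{\mu_i G} - 1)$. Only $G$ needs
integrating, which one classical RK4 step per `dt` does with local error
far below the splitting error (per-step growth exponents are at most a few
percent under the stability-bounded `dt`). After each substep the resource
balance $R' = R - \lambda \sum_i \Delta B_i$ is enforced exactly; if a
step would overdraw the box, $R'$ is clipped at zero and the biomass gains
are capped proportionally. Batch conservation
($\lambda\,\Delta B + \Delta R = 0$) therefore holds to rounding error
over entire runs, independent of integrator accuracy.

**Diffusion.** Forward-Euler 5-point stencil. Toroidal boundaries wrap;
"square" domains use zero-gradient (reflecting) edges — the missing
neighbor takes the edge value — because biomass and resource must not leak
from a closed plate. Both variants conserve each field's total exactly,
and a point release matches the analytic heat kernel to a fraction of a
percent after 150 steps (tested). Under the stability bound the update is
a convex combination, so negative concentrations cannot arise.

**Compiled loop.** The R-level `step()` exists for inspection and
testing; `run_until_consumed()` and the protocol drivers use an Rcpp
loop implementing the *identical* update (a test asserts one compiled
step equals one R-composed step to ~1e-12). Lineages sharing a growth
rate are grouped so drift runs tracking ~50 identical-rate founder
lineages pay one exponential per distinct rate, not per lineage.

**Full/scaled equivalence.** Because the discrete update commutes with the
nondimensionalization (the diffusion number $D\,dt/dx^2$ and the growth
exponents are invariant), a full-model run and the scaled run of its
converted parameters agree field-by-field to rounding error after unit
conversion; the suite checks 1e-6 end-to-end on a 21×21 torus with 3
founders, including the identical step count to the 99%-consumption stop.

**Well-mixed control.** `run_well_mixed` integrates the spaceless ODEs
with `deSolve` (lsodar, root-stopped at 99% consumption). Its independent
check is analytic: all genotypes share the Monod factor, so log fold
changes are exactly proportional to growth rates, and the serial-transfer
version must match a closed-form per-transfer recursion transfer-for-
transfer — which also shows the well-mixed transfer count cannot depend on
$\mu_1$ at a fixed rate ratio.

# Protocols

**Serial transfer.** Founders are seeded at distinct random boxes (one
unit of biomass at a box center), the batch runs until more than 99% of
the resource is consumed, the mutant's biomass fraction is recorded, and
the population is bottlenecked back to `n_founders` cells apportioned by
largest remainder (deterministic, quota-respecting; ties go to the faster
genotype). The next transfer gets fresh random positions and a fresh
resource field. The dilution is deterministic by design — a multinomial
bottleneck is a different experiment. If rounding drives the mutant to
zero founders the run is reported as an extinction rather than looping.
Although the mutant's frequency rises in expectation, at large $\zeta$
founder-placement drift occasionally pushes a single-founder mutant's
share below half a founder quota in an early transfer, so rare
extinctions are a genuine outcome of the protocol; transfer counts are
then reported over the replicates whose mutant invades.

**Chemostat.** Continuous culture adds, in every box,
$\dot R = \delta(R_{\mathrm{res}} - R)$ and $\dot B_i = -\delta B_i$.
These linear terms are applied as their exact exponential update inside
the reaction substep (sub-split after growth), so the only error is
$O(dt^2)$ splitting; the analytic single-species steady state
$R^\* = k\delta/(\mu - \delta)$ is recovered on a fast-equilibrating
lattice in the tests. Runs stop at the mutant-frequency threshold or at
washout (total biomass below one founder unit), which is the guaranteed
outcome when every $\mu_i < \delta$. The chemostat uses a torus, matching
the serial-transfer design.

# Spatial statistics

**Territories.** Voronoi (Dirichlet) areas are computed by discrete
nearest-site assignment: every lattice box joins the founder nearest its
center, ties to the lowest founder index. This matches the lattice world
the biomass actually grows on, guarantees the areas sum exactly to the
domain area, and avoids unbounded-polygon edge cases; it replaces an areal
polygon construction with a discretization of the same object. Toroidal
territories are deliberately unsupported — the localization analysis runs
on square (no-flux) domains to keep the tessellation unambiguous. On
refinement the discrete areas converge as fractions of the domain (halving
`dx` moves each founder's share by well under two percentage points on
random 15-founder maps); the *relative* area of the smallest cells
converges more slowly, as expected for a boundary-dominated quantity.

**Competition localization** is the OLS slope of relative colony biomass
on relative territory area, invariant to rescaling either input: slope ≈ 1
means a colony's final biomass is set by its own territory (local
competition), slope ≈ 0 means the resource pool is effectively shared.

**Genetic drift.** The same neutral runs (every founder its own lineage,
all rates equal) yield, per map, the SD across founders of final lineage
frequency; per $\zeta$, the mean over maps, normalized by the sweep
maximum. With equal rates the *total* final biomass is fixed by
conservation — drift lives entirely in how it is partitioned.

**Drift-free selection.** Founders sit on a translation-symmetric grid on
a torus, so every founder sees an identical neighborhood and drift is
impossible; the central founder grows 10% faster (relative rate 1.1
against ancestors at 1, so in this one assay $\zeta$ is scaled by the
ancestors' unit rate), and the response is its absolute frequency gain
after one batch. With `benefit = 1` the gain vanishes to rounding error, a
symmetry the tests assert at 1e-9.

# The generator and what passing tests show

Founder maps — uniform random distinct boxes, or exact grids — together
with homogeneous initial resource fields are the package's synthetic
inputs; the defaults (49 founders, 100 resource units per box, a 10%
mutant benefit, 5 cm toroidal plates at 101×101 boxes) are the benchmark
conditions of the study design the package implements. The generator does
not emulate features of real plates: spatially heterogeneous agar,
irregular inoculum sizes, cell death, or colonies that alter their own
resource's diffusion. Passing tests therefore demonstrate the internal
consistency of the model and its statistics, not that any particular
organism behaves this way.

# Problem sizes and design choices

The package ships two preset tiers. `"paper"` mirrors the benchmark design
(101×101 or 105×105 lattices; 11 length scales × 2 founder densities × 10
maps for the localization sweep; 20 replicates for invasion).
`"desk"` presets are the package's reduced designs for interactive use and
the test suite: 51×51 (invasion, localization) and 45×45 (selection)
lattices, 3-point sweeps, and 3–10 replicates — sized so each experiment
preserves its qualitative contrast while completing in minutes on one CPU.
Choices the design left open, decided here once: the invasion growth-rate
sweep is {0.01, 0.05, 0.1, 0.2, 0.4}/h across the stated 0.01–0.4 range
(desk: {0.05, 0.15, 0.4}); the 11 localization length scales default to a
geometric sequence over 0.03–3 in scaled box width, spanning the
global-to-local transition ($\zeta \approx$ 0.2–20 at 49 founders); the
drift analysis reuses the localization runs with 10 maps per density;
per-replicate RNG seeds derive from one experiment seed by a counter
scheme recorded in the manifest.

# Limitations

Explicit diffusion makes cost scale as $1/\hat h^2$ per unit time, so
small-$\zeta$ (fast-diffusion) corners of parameter space are the
expensive ones; there is deliberately no implicit or spectral fast path,
since fidelity to the simple explicit scheme is part of the design. The
scaling covers one resource only — multiple resources with distinct
diffusion constants have no single natural length scale. Frequencies are
biomass fractions at the consumption stop; no mutation process exists (the
mutant is present from the first transfer), and the bottleneck is
deterministic, so demographic stochasticity enters only through founder
placement.
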