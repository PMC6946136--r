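# zetasim

Resource-explicit reaction–diffusion simulation of competing microbial
colonies, and the spatial statistics that explain when evolution on a
surface slows down.

## The problem

When microbes grow on a surface (an agar plate, a biofilm), founder cells
form colonies that compete for a single diffusing resource. Whether a
faster-growing mutant can sweep through such a population depends not only
on its growth advantage but on *how local* the competition is: if each
colony only ever consumes the resource in its own neighborhood, a mutant's
advantage is spent on its nearest neighbors and fixation is slow; if the
resource pool is effectively shared, the mutant competes with everyone at
once and invades as fast as in liquid culture.

`zetasim` implements the model and the four in-silico experiments that make
this precise. Genotypes \(B_i\) grow with Monod kinetics on a resource
\(R\), and both diffuse:

$$\partial_t B_i = D_B \nabla^2 B_i + \mu_i B_i \frac{R}{R+k}, \qquad
\partial_t R = D_R \nabla^2 R - \sum_i \lambda\, \mu_i B_i \frac{R}{R+k}$$

Nondimensionalizing (resource in units of \(k\), biomass in \(k/\lambda\),
time in \(1/\mu_1\)) shows that space enters only through the **natural
length scale** \(x_c = \sqrt{D_R/\mu_1}\) — the distance the resource
diffuses in one characteristic growth time. The degree of competition
localization is governed by a single dimensionless number, the **scaled
mean intercolony distance**

$$\zeta = \frac{\overline{IC}}{\sqrt{D_R/\mu_1}},$$

where \(\overline{IC}\) is the mean over colonies of the minimum
center-to-center distance to another colony. Faster growth, sparser
founders, or slower resource diffusion all increase \(\zeta\) and localize
competition — which increases genetic drift and *weakens* selection, so
higher basal growth rates paradoxically slow the invasion of
faster-growing mutants in serial-transfer experiments.

## What the package provides

* **Engine** (`diffuse_step`, `growth_step`, `step`, `run_until_consumed`,
  `run_well_mixed`): operator-split explicit finite differences (5-point
  stencil, `dt = 0.1 dx²/D`) with per-box Monod growth and exact resource
  bookkeeping, on toroidal or no-flux lattices, for the full (cm, h) or
  scaled (dimensionless) parameterization, with a compiled (Rcpp) stepping
  loop. Per-genotype or per-founder-lineage tracking.
* **Scaling** (`full_params`, `scaled_params`, `to_scaled`, `from_scaled`,
  `natural_length_scale`, `compute_zeta`).
* **Protocols** (`run_invasion_spatial`, `run_invasion_well_mixed`,
  `run_chemostat`, `bottleneck`): serial transfers with a deterministic
  largest-remainder bottleneck, and a continuous-dilution chemostat.
* **Spatial statistics** (`mean_nn_distance`, `voronoi_areas`,
  `competition_localization`, `localization_sweep`, `drift_statistic`,
  `selection_assay`): discrete Dirichlet territories, the
  biomass-on-territory regression slope ("competition localization"), the
  neutral-lineage drift statistic, and the drift-free grid selection assay.
* **Experiment drivers** (`run_invasion_experiment`,
  `run_localization_experiment`, `run_selection_experiment`,
  `run_chemostat_experiment`, `run_robustness_experiment`) with `"paper"`
  and `"desk"` presets, YAML configs, CSV outputs, and JSON run manifests;
  a thin CLI lives at `inst/cli/zetasim.R`.

## Worked example

```r
library(zetasim)

p <- full_params(D_B = 5e-9, D_R = 5e-6, mu = c(0.11, 0.10),
                 k = 1, lam = 1, R0 = 100, units = "cm2_per_s")
p
#> Full-model parameters (cm, h):
#>   D_B = 1.8e-05 cm^2/h, D_R = 0.018 cm^2/h
#>   mu  = 0.11, 0.1 1/h (fastest first)
#>   k = 1, lambda = 1, R0 = 100 per box
#>   natural length scale sqrt(D_R/mu1) = 0.40452 cm

to_scaled(p)$scaled
#> Scaled (dimensionless) model parameters:
#>   D_c = 0.001, R0_hat = 100 per box
#>   mu_rel = 1, 0.909091

compute_zeta(ic_bar = 0.45, D_R = p$D_R, mu1 = 0.15)
#> [1] 1.299038
```

The diffusion constants (given here in cm²/s and converted on ingest) are
typical of a small sugar in agar; bacteria diffuse 1000× slower, giving the
relative diffusion constant `D_c = 0.001`, and a 10% growth advantage gives
the ancestor relative rate `1/1.1 ≈ 0.909`. A mean intercolony spacing of
0.45 cm at an ancestor rate of 0.15/h sits at `ζ ≈ 1.3` — competition
reaching a colony's first few neighbors.

A miniature drift-free selection assay (9 founders in a grid on a torus,
the center one growing 10% faster, swept over the natural length scale):

```r
selection_assay(length_scales = c(0.3, 0.6, 1.2), nx = 15,
                n_founders = 9, benefit = 1.1)
#>   length_scale zeta mutant_final_freq delta_freq
#> 1          0.3  1.5         0.1630799 0.05196879
#> 2          0.6  3.0         0.1329606 0.02184947
#> 3          1.2  6.0         0.1224827 0.01137158
```

The mutant starts at frequency 1/9 ≈ 0.111 everywhere; its absolute gain
`delta_freq` shrinks from 0.052 to 0.011 as ζ grows — selection weakens as
competition localizes.

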