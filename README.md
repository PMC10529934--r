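# cagefield

Local-electric-field (LEF) and selectivity analytics for caged
metal-oxo catalysts.

Supramolecular cages enclosing an iron(IV)-oxo porphyrin oxidant steer
C–H hydroxylation through the electric field their charged and polar
groups exert at the Fe=O reaction center: the field along the reaction
axis (*z*, Fe→O) controls reactivity, and the lateral field (*y*)
controls which prochiral hydrogen is abstracted. `cagefield` is for
computational chemists who run such MD/QM/MM design studies and need
the surrounding electrostatic and statistical analysis as tested,
reusable code:

- **Fields from point charges.** `field_at_point()` evaluates the
  Coulomb sum `F = k_C Σ qᵢ (p − rᵢ)/|p − rᵢ|³` (k_C = 14.3996 V·Å/e);
  `build_axis_frame()` + `field_series()` project it per frame on the
  reaction-axis frame with group decomposition.
- **Dipoles and stabilization energies.** `group_dipole()` gives
  `μ = k_D Σ qᵢ (rᵢ − o)` in Debye (k_D = 4.80320 D/e·Å);
  `stabilization_energy()` combines components as
  `ΔE_a = k_E F_a μ_a` (k_E = 4.8009 kcal mol⁻¹ D⁻¹ (V/Å)⁻¹; Gaussian
  convention, negative = stabilizing); `table1_report()` assembles the
  per-state table.
- **Selectivity analytics.** Distance population histograms
  (`population_hist()`), representative-frame selection, π-stacking
  contact occupancy, and Boltzmann barrier-difference ratios
  (`enantiomer_ratio()`, ratio = exp(ΔΔE‡/RT)).
- **Free-energy profiles.** `jarzynski_dg()` implements
  ⟨exp(−βW)⟩ = exp(−βΔG) via log-sum-exp; `asmd_stitch()` stitches
  staged (adaptive steered MD) work traces with bootstrap uncertainty.
- **Synthetic systems with analytic ground truth.**
  `gen_cage_system()`, `gen_distance_series()`, `gen_contact_series()`,
  `gen_work_traces()` emulate the caged-oxidant setting with closed-form
  targets, so every estimator is testable end to end.

Everything is tidyverse-native: tibbles in and out, `autoplot()` for
histograms, field series and profiles, `tidy()`/`glance()` for fitted
profile objects. File formats: PQR topologies, multi-frame XYZ
trajectories, long-form CSV work traces, YAML configs.

## Worked example

Reproducing the per-state stabilization table from printed field and
dipole components:

```r
library(cagefield)
states <- tibble::tibble(
  state = c("RS", "TS1(R)", "TS1(S)"),
  mu    = c(8.87, 13.88, 10.82),
  f_z   = c(-0.29, -0.27, -0.19),
  mu_z  = c(8.67, 13.85, 10.59),
  f_y   = c(0.19, 0.20, 0.23),
  mu_y  = c(1.76, -0.40, 1.66)
)
table1_report(states)
#> # A tibble: 3 × 8
#>   state     mu   f_z  mu_z   de_z   f_y  mu_y   de_y
#>   <chr>  <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>  <dbl>
#> 1 RS      8.87 -0.29  8.67 -12.1   0.19  1.76  1.61
#> 2 TS1(R) 13.9  -0.27 13.8  -18.0   0.2  -0.4  -0.384
#> 3 TS1(S) 10.8  -0.19 10.6   -9.66  0.23  1.66  1.83
```

`de_z` is the reaction-axis field–dipole energy in kcal/mol (negative =
stabilizing): the pro-R transition state is stabilized by ~18 kcal/mol
against ~9.7 for pro-S, while the misoriented pro-S dipole is further
destabilized laterally (`de_y` +1.83). The resulting kinetic preference,
from the 4.8 vs 7.81 kcal/mol abstraction barriers:

```r
enantiomer_ratio(4.8, 7.81, temperature = 298.15)
#> # A tibble: 1 × 5
#>   dd_barrier temperature ratio major percent_major
#>        <dbl>       <dbl> <dbl> <chr>         <dbl>
#> 1       3.01        298.  161. R              99.4
```

i.e. a ~161 : 1 R : S product ratio (99.4 % R). A complete synthetic
study — generated cage system, field time series, stabilization table,
population/occupancy analytics and a stitched free-energy profile —
runs from one config:

```r
demo <- make_demo(seed = 7)
res <- run_full_analysis(demo$config)
glance(res$pmf)
#> # A tibble: 1 × 6
#>   dg_total dg_max n_traj n_stages temperature adaptive
#>      <dbl>  <dbl>  <int>    <int>       <dbl> <lgl>
#> 1     19.0   19.0     20       10         300 TRUE
```

The demo's work traces are drawn around a linear 20 kcal/mol exit
profile; with 20 noisy trajectories the stitched estimate lands at 19.0
kcal/mol with its bootstrap band covering the truth. See the vignette
(`vignettes/cage-field-analysis.Rmd`) for the model, conventions and
numerical choices.

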