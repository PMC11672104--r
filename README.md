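# tncoupling

Phosphorylation of cardiac troponin I at Ser22/23 by protein kinase A
normally lowers the thin filament's Ca²⁺ sensitivity 2–3-fold, which
speeds cardiac relaxation after β-adrenergic stimulation (lusitropy).
Cardiomyopathy mutations such as TnC G159D, TnT R92Q or ACTC E99K
*uncouple* Ca²⁺ sensitivity from phosphorylation, and some small
molecules (silybin B, resveratrol, EGCG) can *recouple* it. The evidence
for recoupling lives at three very different scales, each with its own
measurement conventions:

- **Molecular dynamics of the troponin core** — the distribution of the
  TnC helix A/B interhelix angle (hydrophobic-patch opening; angles
  above 110° taken as the open state), the NcTnC–ITC interdomain hinge
  angle, the interdomain centroid distance, the D159–R83 salt-bridge
  occupancy, and ligand contact/attachment statistics.
- **In vitro motility** — fraction of motile thin filaments versus
  [Ca²⁺], summarised by a four-parameter Hill fit
  f = f_min + (f_max − f_min)/(1 + (EC₅₀/[Ca])^n_H), with coupling
  quantified as the ratio EC₅₀(P)/EC₅₀(unP).
- **Intact cardiomyocytes** — cell-shortening transients at 1 Hz
  pacing, reduced to %L₀ amplitude, ttp₉₀ and ttb₉₀, with lusitropy
  defined as 1 − ttb₉₀(+dobutamine)/ttb₉₀(−dobutamine).

`tncoupling` implements all three analysis tiers as a tidyverse-native R
package — data frames in, tibbles out — together with seeded synthetic
generators that plant known ground truth for every stage (exact rigid
geometric construction for trajectories, Hill curves with known EC₅₀s,
beat templates with known crossing times). That makes the entire
pipeline testable without simulation trajectories or wet-lab recordings,
and makes "does the analysis recover what was planted?" a precise
question. It is aimed at people analysing troponin-dynamics metrics,
motility dose–response data or myocyte contractility records, and at
anyone who wants a fully reproducible stand-in for such data.

## A worked example

Trajectory tier: simulate a wild-type-like run (A/B angle ~
N(101.81°, 9.15°), 3750 frames ≙ 1500 ns at 0.4 ns/frame), then recover
the distribution summary:

```r
library(tncoupling)
library(dplyr)

spec <- trajectory_spec(n_frames = 3750, n_runs = 1)
sim  <- simulate_trajectory(spec, seed = 42)
rg   <- default_regions()
ab   <- ab_angle_series(sim$runs[[1]], rg$helix_a, rg$helix_b)
summarize_distribution(ab, threshold = 110)
#> # A tibble: 1 × 6
#>       n  mean    sd  fwhm pct_above threshold
#>   <int> <dbl> <dbl> <dbl>     <dbl>     <dbl>
#> 1  3750  102.  9.04  21.0      19.1       110
```

The mean (≈101.8°) and sd (≈9.15°) recover the planted distribution;
`pct_above` says ~19% of frames sit in the open state (> 110°), and the
FWHM is close to the Gaussian value 2√(2 ln 2)·σ ≈ 21.5°.

Motility tier: a coupled native-like pair of activation curves
(EC₅₀(unP) = 0.059 µM, planted ratio 2.24):

```r
curves  <- simulate_activation_curves(ec50_unp = 0.059, ratio = 2.24,
                                      noise_sd = 0.02, seed = 42)
fit_unp <- fit_hill(filter(curves, phospho == "uP"))
fit_p   <- fit_hill(filter(curves, phospho == "P"))
fit_unp
#> <hill_fit> EC50 = 0.06282 uM, n_H = 2.31, f = [0.0843, 0.806]
round(coupling_ratio(fit_p, fit_unp), 2)
#> [1] 1.94
```

A ratio near 2 (above the 1.5 coupling threshold) is the coupled
phenotype; uncoupled mutants sit near 1.

Myocyte tier: paired baseline/dobutamine transients with a planted 21%
ttb₉₀ reduction:

```r
pair  <- simulate_dobutamine_pair(ttb90 = 0.5, ttb90_factor = 0.79,
                                  n_cells = 8, seed = 42)
feats <- pair |>
  group_by(cell_id, treatment) |>
  group_modify(~ transient_features(.x)) |>
  ungroup()
paired_response(feats)
#> # A tibble: 4 × 6
#>   measure           n     mean     sem       p_value stars
#>   <chr>         <int>    <dbl>   <dbl>         <dbl> <chr>
#> 1 amplitude_pct     8  3.73    0.101   0.00000000267 **
#> 2 ttp90             8 -0.00717 0.00114 0.000412      **
#> 3 ttb90             8 -0.103   0.00559 0.000000337   **
#> 4 lusitropy         8  0.206   0.00987 0.000000144   **
```

The recovered lusitropy (0.206 ± 0.010) matches the planted 0.21 — a
significantly faster relaxation under dobutamine.

The whole study — every condition at every tier, with
phosphorylation deltas, recoupling calls, coupling calls and the
cross-level agreement matrix — runs as one deterministic pipeline:

```r
report <- run_pipeline(default_config(seed = 1))
report$ab_table
cross_level_summary(report)
```

## Package layout

| Area | Functions |
| --- | --- |
| Structure I/O | `read_topology()`, `read_trajectory()`, `write_trajectory()`, `region()`, `resolve_region()` |
| Trajectory metrics | `ab_angle_series()`, `hinge_angle_series()`, `interdomain_distance_series()`, `pair_bond_occupancy()` |
| Contacts | `residue_contact_series()`, `contact_profile()`, `contact_hotspots()`, `ligand_attachment()` |
| Distribution stats | `summarize_distribution()`, `phospho_delta()`, `classify_recoupling()`, `metric_table()` |
| Motility | `fit_hill()` (+ `tidy()`/`glance()`/`autoplot()`), `coupling_ratio()`, `coupling_call()`, `fixed_ca_screen()` |
| Myocytes | `segment_beats()`, `beat_features()`, `transient_features()`, `lusitropy()`, `paired_response()` |
| Synthetic data | `trajectory_spec()`, `simulate_trajectory()`, `simulate_activation_curves()`, `simulate_transients()`, `simulate_dobutamine_pair()` |
| Pipeline | `default_config()`, `run_pipeline()`, `cross_level_summary()`, `config_hash()` |

The methods vignette (`vignettes/coupling-analysis.Rmd`) documents the
models, conventions, tunable parameters and known limitations.
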