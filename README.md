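# zmatch

Single-subject gray-matter atrophy detection with age-matched normative
references.

## What problem this solves

Voxel-based morphometry can express one patient's gray-matter (GM) map as
voxel-wise Z-statistics against a cognitively normal (CN) reference sample,

```
Z(v) = (x(v) − μ_ref(v)) / σ_ref(v),
```

and summarize atrophy as the number of voxels with `Z` below a threshold
(−2.5, −3.5, −4.5) inside a region of interest — a score that separates
mild cognitive impairment (MCI) from normal aging. But GM declines
nonlinearly across ages 60–90, so the conventional reference built from a
CN sample spanning ~30 years of age over-calls atrophy in old subjects and
misses it in young ones.

`zmatch` is for neuroimaging methodologists who want to build, evaluate
and compare normative reference strategies for this pipeline:

* **standard** whole-sample references (mean/SD of all CN);
* **age-bracket** references — the `k = 20` CN nearest in age within a
  strict ±5 y or ±2.5 y window around the index subject;
* **W-score** models — voxel-wise linear regression of GM on age,
  `W = (x − β₀ − β₁·age) / σ_res`;
* any of these restricted to amyloid-negative CN (SUVR ≤ 1.11).

Evaluation uses subthreshold-voxel extents, Mann–Whitney AUC, Youden
cut-offs, paired DeLong tests between strategies (on the subject
intersection), and Wilcoxon group tests with Bonferroni-interpreted
significance. A first-class synthetic cohort generator — nonlinear
quadratic aging decline, focal medial-temporal MCI atrophy, subtle amyloid
effects, configurable noise — makes the whole pipeline testable without
clinical MRI.

## Worked example

```r
library(zmatch)
library(dplyr)

run <- run_pipeline(run_config(spec = cohort_spec(), seed = 7,
                               kernels = c(0, 2)))
run
#> <zmatch_run: 232 subjects, 26418 extent rows, 126 AUC cells, 134 skips>
#>   best AUC 0.994 (bracket_10y, MTL, Z -2.5, 0 mm)

tidy(run) |>
  filter(roi == "total", z_threshold == -3.5, fwhm_mm == 0) |>
  select(reference_type, auc, ci_lower, ci_upper, n_used)
#>   reference_type   auc ci_lower ci_upper n_used
#> 1 standard       0.828    0.777    0.880    232
#> 2 bracket_10y    0.981    0.959    1        215
#> 3 bracket_5y     0.975    0.948    1        182

run$coverage
#>   reference_type min_age max_age
#> 1 bracket_10y         64      84
#> 2 bracket_5y          66      81
```

The run simulates 141 CN and 91 MCI subjects (ages 73.45 ± 5.75 and
70.84 ± 7.50 y, 24% / 46% amyloid-positive) on a 24³ grid and scores every
subject under each reference strategy, per smoothing kernel. In total GM at
`Z < −3.5`, unsmoothed, the whole-sample reference reaches AUC 0.83 while
the 10-year age brackets reach 0.98 — the age-matching gain the package
exists to quantify. Narrowing to 5-year brackets adds nothing (0.975) but
shrinks the covered sample from 215 to 182 subjects: brackets can only be
built where at least 20 CN fall inside the window (`run$coverage` shows
ages 64–84 vs 66–81 here), and subjects outside that range are recorded in
`run$skips` rather than scored. `autoplot(run)` draws the AUC grid,
`autoplot(run$extents)` the group-wise extent distributions.

Individual stages are exposed directly: `generate_cohort()`,
`gaussian_smooth()`, `select_bracket_members()`, `build_reference()`,
`fit_wscore_model()`, `compute_zmap()` / `compute_wmap()`,
`count_subthreshold()`, `roc_auc()`, `delong_test()`,
`compare_reference_strategies()`, and the replicate-study engine
`simulate_reference_comparison()`. A command-line wrapper lives at
`inst/scripts/zmatch-run.R`. See the vignette
(`vignettes/atrophy-quantification.Rmd`) for the model, parameter
rationale, and what the simulations do and do not demonstrate.

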