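---
title: "Normative Z-map atrophy quantification with age-matched references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative Z-map atrophy quantification with age-matched references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Distinguishing the gray-matter (GM) atrophy of early neurodegeneration —
mild cognitive impairment (MCI) — from the atrophy of cognitively normal
(CN) aging is hard precisely because the two overlap. A widely used
single-subject approach standardizes a patient's spatially normalized,
modulated GM map against a normative CN sample:

$$Z(v) \;=\; \frac{x(v) - \mu_{\mathrm{ref}}(v)}{\sigma_{\mathrm{ref}}(v)}$$

voxel-wise, then counts the voxels below a negative threshold
($Z < -2.5, -3.5, -4.5$) within a region of interest (ROI). That count —
the *subthreshold-voxel extent* — is the per-subject atrophy score entered
into ROC analysis.

The weak point is the reference. Normative samples typically span ~30 years
of age. GM volume declines nonlinearly across 60–90, so a broad-age
reference *overestimates* atrophy in old patients and *underestimates* it
in young ones. `zmatch` implements and compares three remedies:

* **standard** — one reference from the whole CN sample (the status quo);
* **age brackets** — for each subject, the $k = 20$ CN nearest in age
  within a strict half-width window ($\pm 5$ y, a "10-year bracket", or
  $\pm 2.5$ y, a "5-year bracket");
* **W-scores** — voxel-wise linear regression of GM on age in CN,
  $W(v) = \left(x(v) - \hat\beta_0(v) - \hat\beta_1(v)\,a\right) / \hat\sigma_{\mathrm{res}}(v)$,
  which adjusts for age but assumes linearity.

Each reference may further be restricted to amyloid-negative CN
(florbetapir SUVR $\le 1.11$), since amyloid-positive CN carry subtle GM
reductions of their own.

## Reference construction

Bracket membership uses *nearest-k within a strict window*: among CN with
$|a_i - a| < h$, the $k$ closest in age, ties broken by ascending subject
id so selection is reproducible. A window alone with random subsampling
would not be. Reference maps are the voxel-wise arithmetic mean and sample
SD (denominator $n-1$); W-models use residual SD with denominator $n-2$.
These denominators make the member-standardization identity exact: for any
self-included reference, the member Z-values at each voxel have mean 0 and
sample SD 1 by construction, and the test suite asserts this to $10^{-10}$
for every reference it builds.

Bracket coverage is limited: near the age extremes fewer than $k$ CN fall
inside the window and the subject is *skipped* — recorded as data, not an
error. `coverage_ages()` reports the maximal contiguous integer age range a
strategy can serve.

**Self-inclusion.** By default a CN test subject may be a member of its own
reference, mirroring routine practice. This is not innocuous: a subject
contributes to its own mean and SD, shrinking its own Z-scores relative to
out-of-pool subjects. With 20-member brackets the effect is strong enough
that, in a simulation with *zero* diagnostic effect, self-included bracket
scoring yields an AUC whose confidence interval sits wholly above 0.5. The `exclude_self` switch performs leave-one-out
scoring (an $O(p)$ mean/SS downdate for the standard reference); all null
calibration in this package uses it, and the default remains `FALSE` only
because it reproduces what is actually done in the field.

## Scoring and evaluation

Smoothing (Gaussian, FWHM 0/2/4/8 mm, $\sigma = \mathrm{FWHM}/2.3548$, per
axis in voxel units, zero padding at the grid boundary) is applied to GM
maps *before* standardization, and references are rebuilt from smoothed
members per kernel — each kernel is a separate analysis condition.
Z-computation is restricted to a brain mask (reference mean $> \varepsilon$,
default 0.05) and voxels with reference SD below `sd_floor` ($10^{-4}$) are
excluded with NA sentinels and reported per map as `flagged_voxels`, so no
exclusion is silent. Counting uses strict inequality $Z < t$; with
continuous data the choice is measure-zero and fixed for determinism.
Counts are raw voxel numbers (a mm³ column is emitted alongside).

AUC is computed from the Mann–Whitney definition with ties counted ½;
paired AUC comparisons use the DeLong placement-value covariance with a
two-sided normal reference. When the placement difference has numerically
zero variance (e.g. identical score vectors) the comparison is flagged
`degenerate` and $p = 1$ is returned — the zero-difference limit — rather
than a silent 0/0. Operating cut-offs maximize Youden's $J$ and are
reported as midpoints between adjacent distinct scores (hence half-integer
cut-offs on integer counts); ties in $J$ break toward higher specificity,
then toward the lower cut-off. Strategy comparisons are always restricted
to the subjects scored under both strategies — bracket coverage shrinks the
sample, and pairing on the intersection is what makes the DeLong test
valid; the per-strategy AUCs are additionally reported on each strategy's
full scored sample.

Group differences in extents use the Wilcoxon rank-sum test (exact
enumeration for $n_1 + n_2 \le 12$ without ties, tie-corrected normal
approximation with continuity correction otherwise), judged at a raw
$p < 10^{-4}$ with the Bonferroni-corrected level
($10^{-4} \times 216 = 0.0216$ for the default 6 ROI × 3 threshold ×
4 kernel × 3 strategy grid) reported alongside.

## The synthetic cohort generator

Clinical MRI cannot ship with a package, so `zmatch` generates cohorts with
the statistical structure the analysis assumes — and treats the generator
as first-class, tested code. Per subject, voxels in ROI $r$ follow

$$x(v) = g_r(a)\,(1 - e^{\mathrm{amy}}_r A)\,(1 - e^{\mathrm{mci}}_r M)\,s + \epsilon(v),
\qquad g_r(a) = g_{0,r}\,\big(1 - r_1 (a - a_\mathrm{ref}) - r_2 (a - a_\mathrm{ref})^2\big)_+$$

with $A$/$M$ indicating amyloid positivity / MCI, $s$ a lognormal
per-subject global scale and $\epsilon$ iid Gaussian voxel noise, truncated
at 0; background voxels are exactly 0. Defaults (all configurable):

| parameter | default | rationale |
|---|---|---|
| group sizes | 141 CN / 91 MCI | scale of the motivating samples |
| ages | CN 73.45 ± 5.75 y, MCI 70.84 ± 7.50 y, truncated to 60–90, rounded to 0.1 y | roughly normal age distributions at those printed moments |
| amyloid-positive fraction | 24% CN, 46% MCI | printed cohort mixture |
| decline rates $r_1, r_2$ | 0.004 /y, 0.0004 /y² at $a_\mathrm{ref}=70$ | ~0.4%/y linear loss accelerating with age; the nonlinearity is the mechanism that biases broad-age references |
| $g_{0}$ | 0.75–0.85 by ROI | modulated GM concentration scale |
| MCI effect | 15% MTL, 12% temporal, 3–5% elsewhere | focal medial-temporal/temporal atrophy |
| amyloid effect in CN | 2% MTL/temporal, 1% elsewhere | "detectable but subtle"; no published magnitude, exposed in config |
| subject scale sdlog / voxel SD | 0.05 / 0.05 | no published noise model; chosen so bracket-referenced Z-maps have realistic tail counts |
| grid | 24³ at 2 mm | six block ROIs, fast enough for replicate studies |

SUVR values are drawn consistently with the 1.11 positivity rule
(negatives uniform on 0.85–1.10, positives on 1.12–1.60); the label, not
the SUVR magnitude, is what downstream analysis consumes. Each subject has
an RNG stream derived from (cohort seed, subject id), so cohorts are
extensible without reshuffling existing subjects.

The atlas is six disjoint rectangular blocks (MTL, frontal, temporal,
parietal, occipital, other-GM) inside a 2-voxel background border. The
generator emulates *statistical* structure only: no anatomy, no scanner or
site effects, no longitudinal change, spatially independent noise (so
smoothing helps more than it would on spatially correlated real noise).
Passing tests therefore demonstrate the correctness and calibration of the
machinery and the qualitative reference-strategy ordering — not clinical
performance on real MRI.

## What the simulations show

`simulate_reference_comparison()` runs replicate cohorts through one
evaluation cell. Two standing results, asserted by the test suite:

* **Ordering** (20 replicates, default spec, total GM, $Z < -3.5$,
  unsmoothed): the 10-year bracket AUC exceeds the standard-reference AUC
  in essentially every replicate (paired sign test $p < 0.01$), and 5-year
  brackets bring no systematic gain over 10-year brackets while covering
  fewer subjects. The oldest-decile CN show systematically larger extents
  under the standard reference than under brackets (evaluated at $-2.5$,
  the mildest threshold, where normal-range counts are nonzero) — the
  over-calling mechanism in its purest form.
* **Null calibration** (50 replicates, zero effects, *equal* age
  distributions, leave-one-out scoring): AUCs center on 0.5 with ~95% CI
  coverage and standard-vs-bracket DeLong p-values are approximately
  uniform. Both departures from the default configuration are deliberate:
  with unequal age distributions, age alone separates the groups under a
  broad-age reference (that is the effect under study, not a null), and
  with self-inclusion the label is not exchangeable even at zero effect.

## Numerical choices and limitations

Smoothing kernels are sampled Gaussians truncated at $6\sigma$ (tail mass
~$10^{-9}$), so linearity holds to machine precision and the semigroup
property to ~$10^{-6}$ on interior voxels; edge voxels are attenuated by
zero padding, as in standard VBM practice. Grid compatibility demands
identical shape and voxel size — no resampling is implemented, since all
maps are assumed to live on one registration grid. Reference SDs use
two-pass computation. NIfTI output is written as doubles so round-trips are
bit exact.

Problem sizes in the shipped tests and acceptance script — 24³ grids,
141 + 91 subjects, 10–50 replicates — are the package's chosen study scale:
large enough for the sign tests and calibration checks to be decisive,
small enough to run interactively.

Known limitations: no nonlinear normative models (GAMs, quantile
regression); no site harmonization; the W-score covariate set is age only
(head size is assumed handled by modulation); CIs beyond DeLong variance
and cross-validated AUC are out of scope. Real-data AUC tables cannot be
reproduced without the underlying MRI and are not attempted.
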