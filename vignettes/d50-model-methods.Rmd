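---
title: "The D50 progression model and the NfL analysis pipeline: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The D50 progression model and the NfL analysis pipeline: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d50als)
```

## The disease-progression model

Amyotrophic lateral sclerosis erodes motor function along trajectories that
differ enormously between patients, and the standard clinical instrument —
the revised ALS Functional Rating Scale (ALSFRS-R), an integer score from 48
(full function) to 0 — declines curvilinearly, not linearly. The D50 model
summarises each patient's course with a sigmoidal state transition from full
health to functional loss:

$$N(t) = \frac{48}{1 + \exp\!\big((t - D50)/d_x\big)}$$

with `t` the time since reported symptom onset in months. Two parameters
carry the clinical meaning:

* **D50** (months): the time from symptom onset until half of the maximal
  functionality is lost, i.e. `N(D50) = 24` by construction. A small D50 is
  an aggressive course. Patients are stratified as *high* (D50 < 20),
  *intermediate* (20 ≤ D50 < 40) and *low* (40 ≤ D50) aggressiveness, with
  the half-open boundaries implemented exactly as stated.
* **dx** (months): the exponential time constant of the decline — the
  denominator of the exponent above. Across patients dx scales roughly
  linearly with D50 (`d50_dx_relation()` quantifies this), which is what
  justifies using D50 alone as the aggressiveness descriptor.

Normalising time by the individual curve gives the **relative D50**,
`rD50 = t / (2 · D50)`, an open-ended scale on which 0 is symptom onset and
0.5 the half-functionality point regardless of how fast the disease runs.
rD50 at the time of biosampling measures *disease accumulation* — how much of
the course has been covered — as distinct from *aggressiveness*, and is
banded into phases I (< 0.25), II (0.25–0.5) and III/IV (≥ 0.5).

### The onset shift delta

The model admits a presymptomatic phase of up to 6 months before reported
onset, expressed as a bounded shift `delta ∈ [0, 6]` of the latent time
origin. With the plateau fixed at the scale maximum of 48 and D50 reported on
the observed (post-onset) time axis, the shift cancels out of the predicted
score algebraically: shifting the origin by `delta` and moving the internal
half-time by the same amount leaves `48/(1 + exp((t - D50)/dx))` unchanged.
`delta` is therefore not identifiable from ALSFRS-R observations alone. We
keep the parameter in the `d50_fit` record (validated to its bounds, fixable
by the caller via `fix_delta`) for interface completeness, but the optimizer
estimates only `(D50, dx)` and `delta` defaults to 0. The alternative
reading — a supratotal plateau above 48 reached before onset — would make
the shift identifiable in principle, but only through scores above the scale
maximum, which cannot be observed; we chose the shifted-origin form because
it keeps every prediction inside the instrument's range.

### Fitting: numerical choices

`fit_trajectory()` minimises the residual sum of squares under box
constraints `D50 ∈ (0, 300]`, `dx ∈ (0, 150]` months. Initialisation takes
`D50₀` from the linearly interpolated 24-crossing of the observed series
(1.5× the last observation time if the series never crosses 24) and
`dx₀ = D50₀/4`; a five-point multistart scales `dx₀` by {0.25, 0.5, 1, 2, 4}
to escape the flat valleys that sigmoids with few points produce. Ties are
broken by lowest rss, then lowest D50. The L-BFGS-B winner is polished with
bounded Levenberg–Marquardt. Two assessments at two distinct time points are
the minimum (the unique two-parameter sigmoid through two points below 48 has
a closed form, which the test suite uses as an oracle); series that sit
entirely at 48 are rejected as degenerate rather than fitted against the D50
upper bound, because a flat-at-maximum series carries no decline signal.
Tests verify that the returned rss never exceeds the best value on a
100×100 parameter grid, and that noiseless self-generated data are recovered
to 1e-4 relative error.

## The synthetic cohort generator

The generator (`cohort_config()`, `build_cohort()`) reproduces the
*statistical structure* of a cross-sectional CSF NfL biomarker study in ALS,
so the whole pipeline can be exercised and calibrated without clinical data.
Its defaults are the study conditions; they are set once and are not tuning
knobs.

* **Cohort composition**: 156 ALS patients, 56 disease controls, 11 ALS
  mimics, 15 non-neurological controls.
* **D50**: a three-component log-normal mixture with weights 43/61/52 over
  the high/intermediate/low strata and stratum medians 13.62, 28.81 and
  62.58 months; within-stratum spread (SD of log10 D50: 0.174, 0.103, 0.238)
  is back-calculated from the corresponding interquartile ranges. Because a
  draw near a stratum boundary can land in the neighbouring label, the
  labelled-subgroup medians sit slightly inside the targets; the calibration
  tests require agreement within 10%.
* **dx**: `0.28 · D50` plus Gaussian noise (SD 1.5 months), truncated
  positive — the linear coupling above.
* **Assessments**: 5 visits at 3-month spacing straddling the sampling time
  (no within-patient schedule statistics were available to copy, so this is
  a free choice of a typical clinic schedule), scores rounded to integers
  after adding rater noise with SD 2 points and clamped to [0, 48].
* **Sampling shift**: the rD50 at biosampling is Beta-distributed with
  concentration 12 and a mean that rises with aggressiveness (0.37 / 0.25 /
  0.20 at full strength), reproducing the phenomenon that fast progressors
  are referred and sampled later in their relative course. The strength
  parameter interpolates towards a common mean; 0 switches the shift off —
  the mechanism is our construction, only the phenomenon is documented.
* **NfL**: `log10(NfL) = 4.734 − 0.581·log10(D50) + 0.005·(age − 63) +
  0.08·1[lab B] + 0.15·1[FTD] + ε`, ε Gaussian with SD 0.31 chosen so the
  marginal SD of ALS log10 NfL is ≈ 0.37. The intercept and D50 slope are
  the reported regression coefficients; the age, laboratory and FTD effects
  are only reported as significant, so their magnitudes are small positive
  free parameters exposed in the config. Control groups draw log10 NfL
  normal with the reported means/SDs (2.72/0.27, 3.18/0.38, 3.20/0.19).
  Gaussianity on the log10 scale mirrors the study's log-transformation to
  normality.
* **Survival**: the latent death time is the time at which the *true* curve
  crosses ALSFRS-R 12 (`t = D50 + dx·ln(3)`), times a log-normal frailty
  (SD 0.25 on the natural-log scale). Censoring is a Bernoulli indicator at
  the configured fraction (default 59/156); censored patients are observed
  at a uniform fraction of their latent death time. No survival model was
  reported to copy — any generator preserving "higher aggressiveness ⇒
  shorter survival" serves, and threshold-crossing is the simplest one tied
  to the sigmoid. The survival time origin is symptom onset.

What the generator does **not** emulate: genetic strata (C9orf72/SOD1),
repeated NfL sampling, ALSFRS-R subdomain structure, informative censoring,
visit-to-visit correlation of rater error, or real referral dynamics. A
passing pipeline on synthetic cohorts therefore demonstrates internal
statistical correctness and calibration, not clinical validity on real data.

## The statistics engine

* **ROC** (`roc_analysis`): AUC by the rank (Mann–Whitney) formulation, ties
  counted ½ — tests check it against the all-pairs proportion on every
  random draw. The operating cutoff maximises the Youden index
  (sensitivity + specificity − 1); among ties the lowest cutoff is taken.
  The 95% CI uses the Hanley–McNeil normal approximation.
* **ANCOVA** (`ancova`): a linear model with sum-to-zero contrasts and
  Type-III (partial) F tests, matching the reporting convention of
  commercial statistics software; estimated marginal means evaluate
  continuous covariates at their means and weight categorical covariate
  levels equally; pairwise post hocs multiply the raw p by the number of
  pairs (Bonferroni), capped at 1. Collinear covariates raise a
  rank-deficiency error instead of being dropped silently. Constant
  covariates (e.g. a factor collapsing to one level in a small cohort) are
  excluded as uninformative.
* **Mann–Whitney** (`mann_whitney`): U with the tie-corrected normal deviate
  Z; p by exhaustive permutation enumeration when the combined sample is at
  most 20, the normal approximation otherwise.
* **Survival** (`kaplan_meier`, `log_rank`): product-limit estimator and the
  log-rank quadratic form with hypergeometric variance; tests verify the
  statistic against a hand-computed risk-table oracle.
* **Trichotomisation** (`trichotomize_by_emm`): the lowest and highest of the
  three aggressiveness EMMs become marker cutoffs, with half-open intervals
  (a value equal to the lower cutoff is *intermediate*, equal to the upper
  cutoff is *high*).
* **Phase balancing** (`balance_filter`): the study's supplementary filtering
  procedure is not described, so the algorithm is ours: target cell counts
  proportional to the pooled phase distribution, random subsampling within
  cells, best (largest) of 100 seeded draws that pass a chi-square
  independence check at p > 0.5. Phases entirely absent from a stratum are
  dropped by default, or reported as infeasible on request. NfL
  concentrations are analysed as log10 throughout (raw means near 7,000
  pg/mL with a log mean of 3.87 imply base 10).

## The study pipeline

`run_study()` executes the blocks in the order of the original analysis:
diagnostic group summaries with three ROCs (ALS vs each control group), D50
fits, the aggressiveness ANCOVA (covariates age, gender, FTD, laboratory,
phenotype, phase) with Bonferroni post hocs, the phase ANCOVA (with log10
D50 as the continuous aggressiveness covariate, matching its single-df F
test), the phase-balanced ANCOVA, D50–NfL Spearman and log–log regression
overall and within phases, one-way comparisons over UMN/LMN region
categories (none-or-one / two / three-or-four regions), EMM-trichotomised
Kaplan–Meier curves with a log-rank test, and a stratified summary table
(Kruskal–Wallis for continuous, chi-square for categorical comparisons — the
original table does not name its tests). A failing block is marked skipped
with its reason; later blocks still run. Reports serialise to JSON plus a
text rendering, and identical seeds give byte-identical JSON.

## Validation strategy and problem sizes

The reported headline statistics of the motivating study come from an
unavailable clinical cohort, so the package validates against what *is*
reproducible at a desk: distributional parameters and internal consistency.
The test suite (and `scripts/acceptance.R`) uses: three ROC simulations at
the reported group means/SDs and sizes (200–500 replicates each); a
bivariate simulation at the reported R² = 0.313 (500 replicates, n = 156);
exact recovery and oracle-equivalence checks; a 200-patient parameter
recovery study at rater noise SD 2 requiring median relative D50 error
below 15%; 1000 null simulations bounding the ANCOVA type-I error in
[3.5%, 6.5%] at α = 0.05; and 100 full synthetic study replicates requiring
strictly ordered NfL EMMs across aggressiveness strata in at least 95% of
runs. These sizes keep the full suite within a few minutes on one core while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* `delta` is carried but not estimable (see above); fits are effectively
  two-parameter.
* The exponent scaling of dx follows the model equation above; other
  formulations of the same sigmoid may scale the time constant by a factor,
  which would rescale dx but leave D50, rD50, phases and strata unchanged.
* The ANCOVA assumes homogeneous slopes and Gaussian residuals on the log10
  scale; no mixed-effects or repeated-measures variants are provided.
* The survival generator is a convenience mechanism, not a fitted model; no
  Cox regression is included.
* Cutoffs from `trichotomize_by_emm` depend on the aggressiveness ANCOVA
  having exactly three levels.
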