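# d50als

Disease-progression modelling and CSF biomarker analysis for amyotrophic
lateral sclerosis (ALS).

ALS erodes motor function at wildly different speeds between patients, which
confounds any cross-sectional biomarker analysis: a patient sampled late in a
slow course and one sampled early in a fast course can look alike on a single
functional score. `d50als` implements the D50 model, which disentangles
*aggressiveness* from *accumulation*, together with the complete statistical
pipeline used to evaluate cerebrospinal-fluid neurofilament light chain (NfL)
as a prognostic biomarker — and a synthetic cohort generator that makes every
stage testable without clinical data.

The core model fits each patient's longitudinal ALSFRS-R scores (48 = full
function, 0 = complete loss) with a sigmoidal state transition

    N(t) = 48 / (1 + exp((t − D50) / dx))

where **D50** is the time in months from symptom onset to halved
functionality (N(D50) = 24) and **dx** is the time constant of the decline.
D50 stratifies patients into high (< 20), intermediate (20–40) and low
(≥ 40 months) aggressiveness. Normalised time **rD50 = t / (2·D50)** measures
the disease course covered (0 = onset, 0.5 = half functionality) and defines
phases I (< 0.25), II (0.25–0.5) and III/IV (≥ 0.5).

The analysis layer provides rank-based ROC curves with Youden-index cutoffs,
Type-III ANCOVA with estimated marginal means and Bonferroni post hocs,
Spearman/Pearson correlation and log–log regression, exact and approximate
Mann–Whitney tests, Kaplan–Meier curves with log-rank tests, EMM-based
biomarker trichotomisation, and a phase-balancing cohort filter.

## Worked example

Fit one patient's trajectory and locate them on the disease course:

```r
library(d50als)

tr <- data.frame(t_months = c(2, 6, 10, 14, 19),
                 score    = c(46, 43, 38, 30, 22))
fit <- fit_trajectory(tr)
fit
#> D50 sigmoidal decline fit
#>   D50   : 17.64 months (high aggressiveness)
#>   dx    : 5.71 months
#>   delta : 0.00 months
#>   rss   : 3.793 over 5 assessments

relative_d50(12, fit$d50)   # rD50 at a lumbar puncture 12 months after onset
#> [1] 0.3402307
phase_of(relative_d50(12, fit$d50))
#> [1] II
```

This patient loses half their function in under 18 months (an aggressive
course) and was sampled in the early progressive phase II, about a third of
the way through the course.

Run the full study replica on a synthetic cohort (156 ALS patients, three
control groups) and inspect the headline blocks:

```r
report <- run_study(study_config(seed = 42))
report
#> D50/NfL study report (mode = synthetic, seed = 42)
#>
#> Diagnostic performance
#>   ALS                n = 156, log10 NfL mean 3.89 (SD 0.39)
#>   disease_control    n =  56, log10 NfL mean 3.18 (SD 0.49)
#>   mimic              n =  11, log10 NfL mean 3.27 (SD 0.14)
#>   non_neurological   n =  15, log10 NfL mean 2.84 (SD 0.29)
#>   ALS vs disease_control  AUC 0.863 (0.815-0.912), cutoff 3247.8 pg/mL, se 81.4%/sp 78.6%
#>   ALS vs mimic            AUC 0.916 (0.860-0.971), cutoff 3247.8 pg/mL, se 81.4%/sp 100.0%
#>   ALS vs non_neurological AUC 0.986 (0.971-1.001), cutoff 2184.0 pg/mL, se 91.0%/sp 100.0%
#>
#> Aggressiveness ANCOVA
#>   main effect F(2,144) = 9.074, p = 0.000194
#>   EMM high          4.173
#>   EMM intermediate  4.005
#>   EMM low           3.833
#>
#> D50-NfL correlation
#>   Spearman rho = -0.411 (p = 9.89e-08)
#>   log-log regression: slope -0.399, intercept 4.495, R^2 = 0.170
#>
#> Survival by NfL stratum
#>   cutoffs (log10): 3.833 / 4.173; groups n = 61/60/35
#>   log-rank chisq(2) = 23.757, p = 6.94e-06
```

Reading it: CSF NfL separates ALS well from every control group (AUCs
0.86–0.99); after adjusting for age, gender, FTD, laboratory, phenotype and
disease phase, adjusted mean log10 NfL rises strictly with disease
aggressiveness; NfL falls with D50 (more aggressive ⇒ higher NfL); and
trichotomising patients at the EMM-derived NfL cutoffs separates their
survival curves. `write_report()` serialises the full report (all blocks,
including the phase and balance-filtered ANCOVAs, UMN/LMN comparisons and
the stratified summary table) to JSON plus a text rendering, and
`write_cohort()`/`read_cohort()` move cohorts through CSV. A thin CLI with
`simulate` / `fit` / `analyze` / `report` subcommands ships in
`inst/scripts/d50als-cli.R`.

The methods vignette (`vignettes/d50-model-methods.Rmd`) documents the model,
the generator's calibration and every numerical and design choice.

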