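#' Configuration for the synthetic ALS biomarker cohort
#'
#' Bundles every knob of the generator. Defaults reproduce the statistical
#' structure of a cross-sectional CSF NfL study in ALS: 156 ALS patients
#' split over three aggressiveness strata (43 high / 61 intermediate / 52
#' low), stratum D50 log-normal around medians 13.62 / 28.81 / 62.58 months,
#' a linear D50-dx coupling, a sampling shift pushing aggressive patients to
#' later rD50 at lumbar puncture, a log-linear NfL model
#' `log10(NfL) = a + b*log10(D50) + age, laboratory and FTD effects + noise`
#' with a = 4.734 and b = -0.581, control groups with log10 NfL normal around
#' the observed group means/SDs, and threshold-crossing survival with ~37.8%
#' censoring.
#'
#' @param n_als,n_disease_control,n_mimic,n_non_neurological Group sizes.
#' @param strata_weights Mixture weights of the high/intermediate/low
#'   aggressiveness strata (sum to 1).
#' @param d50_medians Within-stratum median D50 in months (high, intermediate,
#'   low).
#' @param d50_sdlog Within-stratum SD of log10 D50.
#' @param dx_slope,dx_noise_sd dx = `dx_slope * d50` + Gaussian noise
#'   (truncated > 0).
#' @param age_mean,age_sd Age at sampling, years (truncated to 18-95).
#' @param n_visits,visit_spacing_months Assessment schedule per patient.
#' @param rater_sd SD of the additive Gaussian rater noise on ALSFRS-R scores.
#' @param nfl_intercept,nfl_slope Intercept and slope of log10 NfL on
#'   log10 D50.
#' @param nfl_age_coef Additive log10 NfL effect per year of age (centred at
#'   `age_mean`).
#' @param nfl_lab_offset Additive log10 NfL offset of laboratory B.
#' @param nfl_ftd_offset Additive log10 NfL offset of comorbid FTD.
#' @param nfl_resid_sd Residual SD of log10 NfL.
#' @param p_lab_b Probability a sample is analyzed in laboratory B.
#' @param p_ftd Prevalence of comorbid frontotemporal dementia.
#' @param p_male Proportion of male patients.
#' @param phenotype_probs Named probabilities of the clinical phenotypes.
#' @param control_log10_mean,control_log10_sd Named log10 NfL mean/SD per
#'   control group (`disease_control`, `mimic`, `non_neurological`).
#' @param shift_strength Sampling-shift strength in \[0, 1\]; 0 makes the
#'   sampling rD50 distribution identical across strata.
#' @param shift_means Target mean sampling rD50 per stratum at strength 1
#'   (high, intermediate, low).
#' @param shift_kappa Concentration of the Beta distribution for sampling rD50.
#' @param survival_threshold ALSFRS-R score whose predicted crossing time is
#'   the latent death time.
#' @param frailty_sdlog SD (natural-log scale) of the multiplicative
#'   log-normal frailty on the death time.
#' @param censor_fraction Expected fraction of censored patients.
#' @param seed Integer seed recorded in the emitted tables.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_als = 156,
                          n_disease_control = 56,
                          n_mimic = 11,
                          n_non_neurological = 15,
                          strata_weights = c(high = 43, intermediate = 61,
                                             low = 52) / 156,
                          d50_medians = c(high = 13.62, intermediate = 28.81,
                                          low = 62.58),
                          d50_sdlog = c(high = 0.174, intermediate = 0.103,
                                        low = 0.238),
                          dx_slope = 0.28,
                          dx_noise_sd = 1.5,
                          age_mean = 63,
                          age_sd = 10,
                          n_visits = 5,
                          visit_spacing_months = 3,
                          rater_sd = 2,
                          nfl_intercept = 4.734,
                          nfl_slope = -0.581,
                          nfl_age_coef = 0.005,
                          nfl_lab_offset = 0.08,
                          nfl_ftd_offset = 0.15,
                          nfl_resid_sd = 0.31,
                          p_lab_b = 1/3,
                          p_ftd = 6/156,
                          p_male = 0.60,
                          phenotype_probs = c(classic = 92, bulbar = 46,
                                              pyramidal = 12, flail_arm = 3,
                                              flail_leg = 1, respiratory = 1,
                                              pure_LMN = 1) / 156,
                          control_log10_mean = c(disease_control = 3.18,
                                                 mimic = 3.20,
                                                 non_neurological = 2.72),
                          control_log10_sd = c(disease_control = 0.38,
                                               mimic = 0.19,
                                               non_neurological = 0.27),
                          shift_strength = 1,
                          shift_means = c(high = 0.37, intermediate = 0.25,
                                          low = 0.20),
                          shift_kappa = 12,
                          survival_threshold = 12,
                          frailty_sdlog = 0.25,
                          censor_fraction = 59/156,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$strata_weights) - 1) > 1e-8)
    stop_d50("d50als_invalid_config", "`strata_weights` must sum to 1.")
  if (abs(sum(cfg$phenotype_probs) - 1) > 1e-8)
    stop_d50("d50als_invalid_config", "`phenotype_probs` must sum to 1.")
  sds <- c(cfg$d50_sdlog, cfg$dx_noise_sd, cfg$rater_sd, cfg$nfl_resid_sd,
           cfg$control_log10_sd, cfg$frailty_sdlog, cfg$age_sd)
  if (any(sds < 0))
    stop_d50("d50als_invalid_config", "All SD parameters must be >= 0.")
  if (cfg$shift_strength < 0 || cfg$shift_strength > 1)
    stop_d50("d50als_invalid_config", "`shift_strength` must lie in [0, 1].")
  if (cfg$censor_fraction < 0 || cfg$censor_fraction >= 1)
    stop_d50("d50als_invalid_config", "`censor_fraction` must lie in [0, 1).")
  structure(cfg, class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Draw one synthetic ALS patient
#'
#' D50 is drawn log-normally within an aggressiveness stratum chosen by the
#' mixture weights; dx follows the linear D50 coupling with truncated Gaussian
#' noise; the sampling rD50 is Beta-distributed with a mean that rises with
#' aggressiveness (the sampling shift), so fast progressors are sampled later
#' in their relative disease course.
#'
#' @param config A [cohort_config].
#' @param patient_id Identifier for the generated record.
#' @return One-row data frame with the patient's latent and observed fields
#'   (true parameters, demographics, sampling time, survival outcome).
#' @export
sample_patient <- function(config, patient_id = "P001") {
  stopifnot(inherits(config, "cohort_config"))
  stratum <- sample(names(config$strata_weights), 1,
                    prob = config$strata_weights)
  true_d50 <- 10^stats::rnorm(1, log10(config$d50_medians[[stratum]]),
                              config$d50_sdlog[[stratum]])
  true_dx <- config$dx_slope * true_d50 +
    stats::rnorm(1, 0, config$dx_noise_sd)
  while (true_dx <= 0.05)
    true_dx <- config$dx_slope * true_d50 +
      stats::rnorm(1, 0, config$dx_noise_sd)
  age <- rtrunc_norm(1, config$age_mean, config$age_sd, 18, 95)

  base_mu <- sum(config$strata_weights * config$shift_means)
  mu <- base_mu + config$shift_strength *
    (config$shift_means[[stratum]] - base_mu)
  mu <- min(max(mu, 0.02), 0.98)
  sampling_rd50 <- stats::rbeta(1, mu * config$shift_kappa,
                                (1 - mu) * config$shift_kappa)

  phen <- sample(names(config$phenotype_probs), 1,
                 prob = config$phenotype_probs)
  rec <- data.frame(
    patient_id = patient_id,
    true_d50 = true_d50,
    true_dx = true_dx,
    age_at_sampling = age,
    gender = sample(c("male", "female"), 1,
                    prob = c(config$p_male, 1 - config$p_male)),
    phenotype = phen,
    ftd = stats::runif(1) < config$p_ftd,
    umn_regions = sample(0:4, 1),
    lmn_regions = sample(0:4, 1),
    sampling_rd50 = sampling_rd50,
    stringsAsFactors = FALSE
  )
  surv <- sample_survival(rec, config)
  rec$survival_months <- surv$survival_months
  rec$event <- surv$event
  rec
}

#' Simulate an ALSFRS-R assessment series for a synthetic patient
#'
#' Visits straddle the sampling time on a regular schedule; observed scores
#' are the true sigmoid plus Gaussian rater noise, rounded to integers and
#' clamped to \[0, 48\].
#'
#' @param patient One-row patient record from [sample_patient].
#' @param config A [cohort_config].
#' @return Data frame with columns `patient_id`, `t_months`, `alsfrs_r`,
#'   times strictly increasing.
#' @export
generate_assessments <- function(patient, config) {
  stopifnot(inherits(config, "cohort_config"))
  fit <- d50_fit(patient$true_d50, patient$true_dx)
  t_samp <- 2 * patient$true_d50 * patient$sampling_rd50
  k <- config$n_visits
  # schedule centred on the sampling time, clipped below at first visit >= 0.5
  t0 <- max(t_samp - config$visit_spacing_months * (k - 1) / 2, 0.5)
  times <- t0 + config$visit_spacing_months * (seq_len(k) - 1)
  truth <- sigmoid_score(times, fit)
  obs <- round(truth + stats::rnorm(k, 0, config$rater_sd))
  obs <- pmin(pmax(obs, 0), 48)
  data.frame(patient_id = patient$patient_id, t_months = times,
             alsfrs_r = obs, stringsAsFactors = FALSE)
}

#' Simulate a CSF NfL measurement for a synthetic ALS patient
#'
#' Log-linear model on the latent aggressiveness:
#' `log10(NfL) = a + b*log10(D50) + c*(age - age_mean) + lab_offset*1[lab B]
#' + ftd_offset*1[FTD] + N(0, sigma)`.
#'
#' @param patient One-row patient record from [sample_patient].
#' @param config A [cohort_config].
#' @return One-row data frame: `patient_id`, `group` ("ALS"), `nfl_pg_ml`,
#'   `log10_nfl`, `laboratory` ("A" or "B").
#' @export
sample_nfl <- function(patient, config) {
  stopifnot(inherits(config, "cohort_config"))
  lab <- if (stats::runif(1) < config$p_lab_b) "B" else "A"
  l10 <- config$nfl_intercept +
    config$nfl_slope * log10(patient$true_d50) +
    config$nfl_age_coef * (patient$age_at_sampling - config$age_mean) +
    config$nfl_lab_offset * (lab == "B") +
    config$nfl_ftd_offset * isTRUE(patient$ftd) +
    stats::rnorm(1, 0, config$nfl_resid_sd)
  data.frame(patient_id = patient$patient_id, group = "ALS",
             nfl_pg_ml = 10^l10, log10_nfl = l10, laboratory = lab,
             t_sampling_months = 2 * patient$true_d50 * patient$sampling_rd50,
             stringsAsFactors = FALSE)
}

#' Simulate CSF NfL for a control group
#'
#' log10 NfL is drawn Normal with the group's configured mean and SD.
#'
#' @param group One of `"disease_control"`, `"mimic"`, `"non_neurological"`.
#' @param n Number of subjects.
#' @param config A [cohort_config].
#' @param id_prefix Prefix for generated subject ids.
#' @return Data frame in the same layout as [sample_nfl].
#' @export
sample_control_group <- function(group, n, config, id_prefix = "C") {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$control_log10_mean))
    stop_d50("d50als_unknown_group",
             sprintf("Unknown control group '%s'.", group))
  l10 <- stats::rnorm(n, config$control_log10_mean[[group]],
                      config$control_log10_sd[[group]])
  data.frame(
    patient_id = sprintf("%s%s%03d", id_prefix, substr(group, 1, 1), seq_len(n)),
    group = group, nfl_pg_ml = 10^l10, log10_nfl = l10,
    laboratory = ifelse(stats::runif(n) < config$p_lab_b, "B", "A"),
    t_sampling_months = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a censored survival outcome tied to the decline curve
#'
#' The latent death time is the time at which the patient's true sigmoid
#' crosses a low functional threshold, multiplied by a log-normal frailty.
#' A Bernoulli draw at the configured censoring fraction decides censoring;
#' censored patients are observed at a uniform fraction of their latent death
#' time.
#'
#' @param patient One-row patient record (needs `true_d50`, `true_dx`).
#' @param config A [cohort_config].
#' @return List with `survival_months` and logical `event` (TRUE = death or
#'   tracheostomy observed).
#' @export
sample_survival <- function(patient, config) {
  stopifnot(inherits(config, "cohort_config"))
  # crossing time of score s: t = d50 + dx * log(48/s - 1)
  s <- config$survival_threshold
  t_death <- patient$true_d50 +
    patient$true_dx * log(48 / s - 1)
  t_death <- t_death * exp(stats::rnorm(1, 0, config$frailty_sdlog))
  t_death <- max(t_death, 0.1)
  censored <- stats::runif(1) < config$censor_fraction
  if (censored) {
    list(survival_months = t_death * stats::runif(1), event = FALSE)
  } else {
    list(survival_months = t_death, event = TRUE)
  }
}

#' Build a full synthetic cohort
#'
#' Generates the three linked tables of the study: `patients` (one row per ALS
#' patient with latent parameters, demographics and survival), `assessments`
#' (longitudinal ALSFRS-R series) and `samples` (one CSF NfL measurement per
#' subject, ALS and control groups). The seed is set at entry and recorded, so
#' the same config yields identical tables.
#'
#' @param config A [cohort_config].
#' @return List of class `synthetic_cohort` with elements `patients`,
#'   `assessments`, `samples`, `config`.
#' @examples
#' coh <- build_cohort(cohort_config(n_als = 5, n_disease_control = 3,
#'                                   n_mimic = 2, n_non_neurological = 2))
#' head(coh$patients)
#' @export
build_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pats <- vector("list", config$n_als)
  asmt <- vector("list", config$n_als)
  nfl <- vector("list", config$n_als)
  for (i in seq_len(config$n_als)) {
    p <- sample_patient(config, sprintf("ALS%04d", i))
    pats[[i]] <- p
    asmt[[i]] <- generate_assessments(p, config)
    nfl[[i]] <- sample_nfl(p, config)
  }
  empty_p <- data.frame(patient_id = character(0), true_d50 = numeric(0),
                        true_dx = numeric(0), age_at_sampling = numeric(0),
                        gender = character(0), phenotype = character(0),
                        ftd = logical(0), umn_regions = integer(0),
                        lmn_regions = integer(0), sampling_rd50 = numeric(0),
                        survival_months = numeric(0), event = logical(0))
  empty_a <- data.frame(patient_id = character(0), t_months = numeric(0),
                        alsfrs_r = numeric(0))
  empty_s <- data.frame(patient_id = character(0), group = character(0),
                        nfl_pg_ml = numeric(0), log10_nfl = numeric(0),
                        laboratory = character(0),
                        t_sampling_months = numeric(0))
  patients <- if (config$n_als) do.call(rbind, pats) else empty_p
  assessments <- if (config$n_als) do.call(rbind, asmt) else empty_a
  samples <- rbind(
    if (config$n_als) do.call(rbind, nfl) else empty_s,
    if (config$n_disease_control)
      sample_control_group("disease_control", config$n_disease_control, config)
    else empty_s,
    if (config$n_mimic)
      sample_control_group("mimic", config$n_mimic, config) else empty_s,
    if (config$n_non_neurological)
      sample_control_group("non_neurological", config$n_non_neurological,
                           config) else empty_s
  )
  rownames(patients) <- rownames(assessments) <- rownames(samples) <- NULL
  structure(list(patients = patients, assessments = assessments,
                 samples = samples, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ALS biomarker cohort\n")
  cat(sprintf("  ALS patients : %d (%d assessments)\n",
              nrow(x$patients), nrow(x$assessments)))
  cat(sprintf("  NfL samples  : %d (%s)\n", nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  cat(sprintf("  seed         : %d\n", x$config$seed))
  invisible(x)
}
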