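#' Analysis configuration for a full study run
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or `"files"`
#'   (read the three CSVs named in `paths`).
#' @param cohort A [cohort_config] (synthetic mode).
#' @param paths Named list/vector with `patients`, `assessments`, `samples`
#'   (file mode).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the stochastic stages (cohort generation, phase
#'   balancing).
#' @return List of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "files"),
                         cohort = cohort_config(),
                         paths = NULL,
                         alpha = 0.05,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" &&
      (is.null(paths) ||
       !all(c("patients", "assessments", "samples") %in% names(paths))))
    stop_d50("d50als_invalid_config",
             "File mode needs `paths` with patients, assessments, samples.")
  structure(list(mode = mode, cohort = cohort, paths = paths,
                 alpha = alpha, seed = as.integer(seed)),
            class = "study_config")
}

run_block <- function(expr) {
  tryCatch(expr, error = function(e)
    list(skipped = TRUE, reason = conditionMessage(e)))
}

region_category <- function(n) {
  # clinical convention: 1 = none or one region, 2 = two, 3 = three or four
  cut(n, breaks = c(-Inf, 1, 2, Inf), labels = c("1", "2", "3"))
}

#' Run the full biomarker study
#'
#' Executes the complete analysis sequence on a synthetic or file-based
#' cohort: group comparisons and three ROC analyses (ALS vs each control
#' group), per-patient D50 fits, the disease-aggressiveness ANCOVA with
#' Bonferroni post hocs, the disease-phase ANCOVA, a phase-balanced repeat of
#' the aggressiveness ANCOVA, D50-NfL Spearman correlation and log-log
#' regression (overall and within phases), one-way comparisons over UMN/LMN
#' region counts, EMM-based NfL trichotomization with Kaplan-Meier curves and
#' a log-rank test, and a stratified cohort summary table. Failures in one
#' block mark it skipped (with the reason) without aborting later blocks.
#'
#' @param config A [study_config].
#' @return List of class `d50_study_report` with one element per analysis
#'   block, plus `seed` and `alpha`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (config$mode == "synthetic") {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$seed
    cohort <- build_cohort(cohort_cfg)
  } else {
    cohort <- read_cohort(config$paths[["patients"]],
                          config$paths[["assessments"]],
                          config$paths[["samples"]])
  }
  set.seed(config$seed)
  patients <- cohort$patients
  samples <- cohort$samples
  als_samp <- samples[samples$group == "ALS", , drop = FALSE]

  report <- list(seed = config$seed, alpha = config$alpha,
                 mode = config$mode)

  # --- diagnostic block: group summaries + three ROCs ----------------------
  report$diagnostic <- run_block({
    l10 <- if ("log10_nfl" %in% names(samples) &&
               !all(is.na(samples$log10_nfl))) samples$log10_nfl
           else log10(samples$nfl_pg_ml)
    groups <- split(l10, samples$group)
    summ <- lapply(groups, function(v)
      list(n = length(v), mean = mean(v), sd = stats::sd(v)))
    rocs <- list()
    for (ctrl in c("disease_control", "mimic", "non_neurological")) {
      if (!is.null(groups[[ctrl]]) && length(groups[[ctrl]])) {
        rr <- roc_analysis(groups[["ALS"]], groups[[ctrl]])
        rocs[[ctrl]] <- list(auc = rr$auc, auc_ci = rr$auc_ci,
                             cutoff_pg_ml = 10^rr$optimal_cutoff,
                             sensitivity = rr$sensitivity,
                             specificity = rr$specificity)
      }
    }
    list(group_log10_nfl = summ, roc = rocs)
  })

  # --- D50 fits ------------------------------------------------------------
  report$fits <- run_block({
    st <- if ("t_sampling_months" %in% names(als_samp))
      data.frame(patient_id = als_samp$patient_id,
                 t_sampling_months = als_samp$t_sampling_months)
    else NULL
    fits <- suppressWarnings(fit_cohort(cohort$assessments, st))
    fits
  })
  fits <- if (is.data.frame(report$fits)) report$fits else NULL

  # assemble the per-patient analysis frame
  als <- NULL
  if (!is.null(fits) && nrow(fits)) {
    als <- merge(fits, patients, by = "patient_id")
    als <- merge(als, als_samp[, setdiff(names(als_samp), "group")],
                 by = "patient_id")
    if (!"log10_nfl" %in% names(als) || all(is.na(als$log10_nfl)))
      als$log10_nfl <- log10(als$nfl_pg_ml)
    als$aggressiveness <- factor(als$aggressiveness,
                                 levels = c("high", "intermediate", "low"))
    if (!"phase" %in% names(als)) als$phase <- NA_character_
    als$phase <- factor(als$phase, levels = c("I", "II", "III_IV"))
  }

  covs <- function(d, extra = NULL) {
    out <- data.frame(age = d$age_at_sampling, gender = factor(d$gender),
                      ftd = factor(d$ftd), laboratory = factor(d$laboratory),
                      phenotype = factor(d$phenotype))
    if (!is.null(extra)) out <- cbind(out, extra)
    out
  }

  # --- aggressiveness ANCOVA ----------------------------------------------
  report$aggressiveness_ancova <- run_block({
    stopifnot(!is.null(als))
    a <- ancova(als$log10_nfl, als$aggressiveness,
                covs(als, data.frame(phase = als$phase)))
    a$model <- NULL
    a
  })

  # --- phase ANCOVA (aggressiveness as continuous log10 D50 covariate) ----
  report$phase_ancova <- run_block({
    stopifnot(!is.null(als))
    a <- ancova(als$log10_nfl, als$phase,
                covs(als, data.frame(log10_d50 = log10(als$d50))))
    a$model <- NULL
    a
  })

  # --- balance-filtered aggressiveness ANCOVA ------------------------------
  report$filtered_ancova <- run_block({
    stopifnot(!is.null(als))
    flt <- balance_filter(als)
    a <- ancova(flt$log10_nfl, droplevels(flt$aggressiveness),
                covs(flt, data.frame(phase = droplevels(flt$phase))))
    a$model <- NULL
    c(a, list(n_retained = nrow(flt), chisq_p = attr(flt, "chisq_p")))
  })

  # --- correlation / regression -------------------------------------------
  report$correlation <- run_block({
    stopifnot(!is.null(als))
    overall <- correlations(als$d50, als$nfl_pg_ml)
    reg <- linear_fit(log10(als$d50), als$log10_nfl)
    by_phase <- lapply(split(als, als$phase), function(d) {
      if (nrow(d) < 3) return(list(skipped = TRUE, reason = "fewer than 3"))
      c(correlations(d$d50, d$nfl_pg_ml)["spearman"], list(n = nrow(d)))
    })
    rd50 <- correlations(als$rd50_at_sampling, als$nfl_pg_ml)
    shift <- correlations(als$d50, als$rd50_at_sampling)
    list(spearman_d50_nfl = overall$spearman,
         regression_loglog = reg,
         spearman_by_phase = by_phase,
         spearman_rd50_nfl = rd50$spearman,
         spearman_d50_rd50 = shift$spearman)
  })

  # --- FTD and phenotype comparisons --------------------------------------
  report$phenotype_ftd <- run_block({
    stopifnot(!is.null(als))
    phen <- stats::oneway.test(log10_nfl ~ phenotype, data = als,
                               var.equal = TRUE)
    mw <- if (length(unique(als$ftd)) == 2)
      mann_whitney(als$log10_nfl[als$ftd %in% c(TRUE, "TRUE")],
                   als$log10_nfl[als$ftd %in% c(FALSE, "FALSE")])
    else list(skipped = TRUE, reason = "single FTD level")
    list(phenotype_anova = list(F = unname(phen$statistic),
                                df1 = unname(phen$parameter[1]),
                                df2 = unname(phen$parameter[2]),
                                p = phen$p.value),
         ftd_mann_whitney = mw)
  })

  # --- UMN / LMN region comparisons ---------------------------------------
  report$umn_lmn <- run_block({
    stopifnot(!is.null(als))
    one_way <- function(v) {
      cat3 <- region_category(v)
      ft <- stats::oneway.test(als$log10_nfl ~ cat3, var.equal = TRUE)
      list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
           df2 = unname(ft$parameter[2]), p = ft$p.value)
    }
    list(umn = one_way(als$umn_regions),
         lmn = one_way(als$lmn_regions),
         combined = one_way(als$umn_regions + als$lmn_regions))
  })

  # --- survival: EMM trichotomization + KM + log-rank ---------------------
  report$survival <- run_block({
    stopifnot(!is.null(als))
    agg <- report$aggressiveness_ancova
    stopifnot(is.null(agg$skipped))
    emms <- sort(agg$emmeans$emmean)
    strata <- trichotomize_by_emm(emms, als$log10_nfl)
    idx <- Filter(length, split(seq_len(nrow(als)), strata))
    km <- lapply(idx, function(i) {
      k <- kaplan_meier(als$survival_months[i], als$event[i])
      list(n = k$n, n_events = k$n_events, median = k$median,
           curve = k$curve)
    })
    lr <- log_rank(als$survival_months, als$event, strata)
    list(cutoffs = c(emms[1], emms[3]),
         group_n = as.list(table(strata)),
         km = km, log_rank = lr)
  })

  # --- stratified cohort summary (Table-1 style) ---------------------------
  report$summary <- run_block({
    stopifnot(!is.null(als))
    cohort_summary(als)
  })

  structure(report, class = "d50_study_report")
}

med_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Stratified cohort summary table
#'
#' Summarizes an analyzed ALS cohort by aggressiveness stratum: NfL, age,
#' gender, D50, rD50 at sampling, disease phase, ALSFRS-R-derived progression
#' metrics. Continuous variables are compared across strata with
#' Kruskal-Wallis tests, categorical ones with chi-square tests.
#'
#' @param als Per-patient analysis frame (needs `aggressiveness`, `nfl_pg_ml`,
#'   `age_at_sampling`, `gender`, `d50`, `rd50_at_sampling`, `phase`).
#' @return List with per-stratum summaries and the comparison p-values.
#' @export
cohort_summary <- function(als) {
  g <- droplevels(factor(als$aggressiveness,
                         levels = c("high", "intermediate", "low")))
  by_g <- split(als, g)
  strata <- lapply(by_g, function(d) list(
    n = nrow(d),
    nfl_pg_ml = med_iqr(d$nfl_pg_ml),
    age = list(mean = mean(d$age_at_sampling),
               sd = stats::sd(d$age_at_sampling)),
    gender = as.list(table(factor(d$gender, levels = c("male", "female")))),
    d50 = med_iqr(d$d50),
    rd50 = med_iqr(d$rd50_at_sampling),
    phase = as.list(table(factor(d$phase, levels = c("I", "II", "III_IV"))))
  ))
  p <- list(
    nfl = stats::kruskal.test(als$nfl_pg_ml, g)$p.value,
    age = stats::kruskal.test(als$age_at_sampling, g)$p.value,
    gender = suppressWarnings(
      stats::chisq.test(table(g, als$gender))$p.value),
    rd50 = stats::kruskal.test(als$rd50_at_sampling, g)$p.value,
    phase = suppressWarnings(
      stats::chisq.test(table(g, als$phase))$p.value)
  )
  list(strata = strata, p_values = p)
}

#' Interlaboratory agreement of paired NfL measurements
#'
#' @param lab_a,lab_b Paired raw NfL concentrations (pg/mL) of the same
#'   samples measured in two laboratories; n >= 3.
#' @return List with `r` (Pearson correlation of the log10 values, with p),
#'   `mean_cv_percent` and `sd_cv_percent` (per-pair coefficient of variation,
#'   SD of the two raw values over their mean, in percent).
#' @export
paired_lab_correlation <- function(lab_a, lab_b) {
  keep <- is.finite(lab_a) & is.finite(lab_b)
  lab_a <- lab_a[keep]; lab_b <- lab_b[keep]
  if (length(lab_a) < 3)
    stop_d50("d50als_too_few_pairs", "At least 3 paired measurements needed.")
  ct <- stats::cor.test(log10(lab_a), log10(lab_b))
  cv <- apply(cbind(lab_a, lab_b), 1,
              function(v) stats::sd(v) / mean(v) * 100)
  list(r = unname(ct$estimate), p = ct$p.value,
       mean_cv_percent = mean(cv), sd_cv_percent = stats::sd(cv))
}

#' @export
print.d50_study_report <- function(x, ...) {
  cat(sprintf("D50/NfL study report (mode = %s, seed = %d)\n\n",
              x$mode, x$seed))
  blk <- function(name, title, body) {
    b <- x[[name]]
    cat(title, "\n")
    if (is.null(b)) { cat("  (absent)\n\n"); return(invisible()) }
    if (isTRUE(b$skipped)) {
      cat("  skipped:", b$reason, "\n\n"); return(invisible())
    }
    body(b); cat("\n")
  }
  blk("diagnostic", "Diagnostic performance", function(b) {
    for (g in names(b$group_log10_nfl)) {
      s <- b$group_log10_nfl[[g]]
      cat(sprintf("  %-18s n = %3d, log10 NfL mean %.2f (SD %.2f)\n",
                  g, s$n, s$mean, s$sd))
    }
    for (g in names(b$roc)) {
      r <- b$roc[[g]]
      cat(sprintf("  ALS vs %-16s AUC %.3f (%.3f-%.3f), cutoff %.1f pg/mL, se %.1f%%/sp %.1f%%\n",
                  g, r$auc, r$auc_ci[1], r$auc_ci[2], r$cutoff_pg_ml,
                  100 * r$sensitivity, 100 * r$specificity))
    }
  })
  blk("aggressiveness_ancova", "Aggressiveness ANCOVA", function(b) {
    i <- which(b$terms$term == "group")
    cat(sprintf("  main effect F(%d,%d) = %.3f, p = %.3g\n",
                b$terms$df1[i], b$terms$df2[i], b$terms$F[i], b$terms$p[i]))
    for (j in seq_len(nrow(b$emmeans)))
      cat(sprintf("  EMM %-13s %.3f\n", b$emmeans$level[j],
                  b$emmeans$emmean[j]))
  })
  blk("correlation", "D50-NfL correlation", function(b) {
    cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n",
                b$spearman_d50_nfl$rho, b$spearman_d50_nfl$p))
    cat(sprintf("  log-log regression: slope %.3f, intercept %.3f, R^2 = %.3f\n",
                b$regression_loglog$slope, b$regression_loglog$intercept,
                b$regression_loglog$r_squared))
  })
  blk("survival", "Survival by NfL stratum", function(b) {
    cat(sprintf("  cutoffs (log10): %.3f / %.3f; groups n = %s\n",
                b$cutoffs[1], b$cutoffs[2],
                paste(unlist(b$group_n), collapse = "/")))
    cat(sprintf("  log-rank chisq(%d) = %.3f, p = %.3g\n",
                b$log_rank$df, b$log_rank$chisq, b$log_rank$p))
  })
  invisible(x)
}
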