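#' ROC analysis with Youden-index cutoff
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation — the proportion
#' of (positive, negative) pairs in which the positive value exceeds the
#' negative, with ties counted one half — so higher values indicate the
#' positive class. The operating cutoff maximizes the Youden index
#' (sensitivity + specificity - 1); among maximizers the lowest cutoff is
#' chosen. The 95% AUC confidence interval uses the Hanley-McNeil normal
#' approximation.
#'
#' @param positives Marker values in the positive class (e.g. log10 NfL in
#'   ALS).
#' @param negatives Marker values in the negative class.
#' @return List of class `roc_result`: `auc`, `auc_ci` (length-2), `se`,
#'   `optimal_cutoff`, `sensitivity`, `specificity` (at the cutoff), and a
#'   `curve` data frame of (cutoff, sensitivity, specificity) points.
#' @examples
#' roc_analysis(rnorm(50, 1), rnorm(50, 0))
#' @export
roc_analysis <- function(positives, negatives) {
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  if (!length(positives) || !length(negatives))
    stop_d50("d50als_empty_group", "Both groups must be non-empty.")
  n1 <- length(positives); n0 <- length(negatives)
  r <- rank(c(positives, negatives))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- c(auc - 1.96 * se, auc + 1.96 * se)

  cuts <- sort(unique(c(positives, negatives)))
  sens <- vapply(cuts, function(ct) mean(positives >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(negatives < ct), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1] # lowest cutoff among maximizers
  structure(
    list(auc = auc, auc_ci = ci, se = se,
         optimal_cutoff = cuts[best],
         sensitivity = sens[best], specificity = spec[best],
         curve = data.frame(cutoff = cuts, sensitivity = sens,
                            specificity = spec)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$optimal_cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' One-way ANCOVA with estimated marginal means
#'
#' Linear model of a (log-transformed) response on a grouping factor plus
#' covariates, with Type-III (partial) F tests, estimated marginal means per
#' factor level (continuous covariates at their means, categorical covariate
#' levels equally weighted), and Bonferroni-adjusted pairwise post hoc
#' contrasts of the EMMs.
#'
#' @param response Numeric response (e.g. log10 NfL).
#' @param factor Grouping factor of interest (>= 2 levels, each with >= 2
#'   observations).
#' @param covariates Optional data frame of covariates (numeric or factor
#'   columns), same length as `response`.
#' @return List of class `ancova_result`: `terms` (data frame: term, F, df1,
#'   df2, p), `emmeans` (data frame: level, emmean, se, lower, upper),
#'   `posthoc` (data frame: contrast, estimate, p_adj), `model` (the `lm`
#'   fit).
#' @export
ancova <- function(response, factor, covariates = NULL) {
  factor <- droplevels(as.factor(factor))
  if (nlevels(factor) < 2)
    stop_d50("d50als_single_level",
             "The grouping factor needs at least two levels.")
  if (any(table(factor) < 2))
    stop_d50("d50als_single_level",
             "Every factor level needs at least two observations.")
  dat <- data.frame(.y = response, .g = factor)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(response))
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      dat[[nm]] <- if (is.character(v) || is.logical(v)) factor(v) else v
      if (is.factor(dat[[nm]])) dat[[nm]] <- droplevels(dat[[nm]])
    }
    # constant covariates carry no information and break the design
    keep <- vapply(names(covariates), function(nm) {
      v <- dat[[nm]]
      if (is.factor(v)) nlevels(v) >= 2 else stats::sd(v) > 0
    }, logical(1))
    cov_terms <- names(covariates)[keep]
  }
  fml <- stats::reformulate(c(".g", cov_terms), response = ".y")
  # sum-to-zero contrasts so Type-III tests are meaningful
  contr <- lapply(Filter(function(nm) is.factor(dat[[nm]]),
                         c(".g", cov_terms)),
                  function(nm) "contr.sum")
  names(contr) <- Filter(function(nm) is.factor(dat[[nm]]), c(".g", cov_terms))
  model <- stats::lm(fml, data = dat, contrasts = contr)
  if (any(is.na(stats::coef(model))))
    stop_d50("d50als_rank_deficient",
             "Rank-deficient design: collinear covariates.")
  a3 <- car::Anova(model, type = 3)
  rows <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  df2 <- a3["Residuals", "Df"]
  terms <- data.frame(
    term = ifelse(rows == ".g", "group", rows),
    F = a3[rows, "F value"], df1 = a3[rows, "Df"], df2 = df2,
    p = a3[rows, "Pr(>F)"], row.names = NULL)
  em <- emmeans::emmeans(model, ".g")
  ems <- as.data.frame(em)
  emmeans_df <- data.frame(level = as.character(ems$.g),
                           emmean = ems$emmean, se = ems$SE,
                           lower = ems$lower.CL, upper = ems$upper.CL)
  ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "bonferroni"))
  posthoc <- data.frame(contrast = as.character(ph$contrast),
                        estimate = ph$estimate, se = ph$SE,
                        p_adj = ph$p.value)
  structure(list(terms = terms, emmeans = emmeans_df, posthoc = posthoc,
                 model = model),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("ANCOVA (Type-III F tests)\n")
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %-14s F(%d,%d) = %.3f, p = %.4g\n",
                x$terms$term[i], x$terms$df1[i], x$terms$df2[i],
                x$terms$F[i], x$terms$p[i]))
  cat("Estimated marginal means:\n")
  for (i in seq_len(nrow(x$emmeans)))
    cat(sprintf("  %-14s %.3f (SE %.3f)\n", x$emmeans$level[i],
                x$emmeans$emmean[i], x$emmeans$se[i]))
  invisible(x)
}

#' Pearson and Spearman correlation
#'
#' @param x,y Paired numeric vectors, n >= 3. Spearman uses average ranks for
#'   ties.
#' @return List with `pearson` (`r`, `p`) and `spearman` (`rho`, `p`).
#' @export
correlations <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_d50("d50als_too_few_pairs", "At least 3 complete pairs are required.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_d50("d50als_zero_variance", "Correlation undefined: zero variance.")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(rho = unname(sp$estimate), p = sp$p.value))
}

#' Simple linear regression
#'
#' @param x,y Paired numeric vectors, n >= 3, `x` non-constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope test).
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_d50("d50als_too_few_pairs", "At least 3 complete pairs are required.")
  if (stats::sd(x) == 0)
    stop_d50("d50als_zero_variance", "`x` must not be constant.")
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = NA_real_))
  m <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(m)) # perfect fits are legitimate here
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       r_squared = sm$r.squared,
       p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two independent samples. Reports the U statistic
#' for the first sample, the tie-corrected normal deviate Z, and a p-value:
#' exact (by enumeration of the permutation distribution of U) when both
#' samples are small and the normal approximation with tie correction
#' otherwise.
#'
#' @param x,y Numeric samples; both non-empty.
#' @param exact_max Use exact enumeration when `length(x) + length(y)` is at
#'   most this (default 20).
#' @return List with `U`, `Z`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 20) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop_d50("d50als_empty_group", "Both groups must be non-empty.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)

  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0

  if (n <= exact_max) {
    # enumerate all assignments of ranks to group 1
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    u_all_min <- pmin(u_all, n1 * n2 - u_all)
    p <- mean(u_all_min <= u + 1e-9)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = u, Z = z, p = min(p, 1), method = method)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function.
#'
#' @param times Follow-up times (> 0), months.
#' @param events Logical/0-1 event indicators (TRUE = death or tracheostomy).
#' @return List of class `km_curve`: `curve` data frame (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `median` survival (NA if never below
#'   0.5), `n`, `n_events`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop_d50("d50als_invalid_times", "`times` must be finite and > 0.")
  events <- as.logical(events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(sf)$table["median"])
  structure(
    list(curve = data.frame(time = sf$time, n_risk = sf$n.risk,
                            n_event = sf$n.event, n_censor = sf$n.censor,
                            surv = sf$surv),
         median = med, n = length(times), n_events = sum(events)),
    class = "km_curve")
}

#' Log-rank test
#'
#' Compares the survival experience of two or more groups with the standard
#' log-rank quadratic form (observed minus expected events, hypergeometric
#' variance).
#'
#' @param times Follow-up times (> 0).
#' @param events Logical event indicators.
#' @param groups Group labels (>= 2 groups with observations).
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank <- function(times, events, groups) {
  events <- as.logical(events)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop_d50("d50als_single_level", "Log-rank needs at least two groups.")
  if (!any(events))
    stop_d50("d50als_no_events", "Log-rank undefined: no events observed.")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Trichotomize values at EMM-derived cutoffs
#'
#' Splits a marker into low / intermediate / high using the lowest and highest
#' of three ordered estimated marginal means as cutoffs, with half-open
#' intervals: low (`value < emm1`), intermediate (`emm1 <= value < emm3`),
#' high (`emm3 <= value`).
#'
#' @param emms Three EMMs sorted ascending.
#' @param values Numeric marker values (e.g. log10 NfL).
#' @return Factor with levels `"low"`, `"intermediate"`, `"high"`.
#' @export
trichotomize_by_emm <- function(emms, values) {
  if (length(emms) != 3 || is.unsorted(emms, strictly = FALSE))
    stop_d50("d50als_unsorted_emms",
             "`emms` must be three values sorted ascending.")
  cut(values, breaks = c(-Inf, emms[1], emms[3], Inf),
      labels = c("low", "intermediate", "high"), right = FALSE)
}

#' Phase-balance a cohort by random subsampling
#'
#' Draws a random subsample in which the disease phases are proportionally
#' distributed across the aggressiveness strata, so that phase can serve as an
#' ANCOVA covariate without violating the homogeneity assumption. Target cell
#' counts follow the pooled phase distribution; among `attempts` seeded draws
#' the one passing a chi-square independence check at p > 0.5 with the
#' largest retained n wins. Phases absent from some stratum are dropped
#' (default) or raise an error.
#'
#' @param cohort Data frame with columns `aggressiveness` and `phase`.
#' @param attempts Number of random draws (default 100).
#' @param drop_empty_phase Drop phases missing from any stratum (default TRUE);
#'   if FALSE, such a table raises an infeasibility error.
#' @return Subsample of `cohort` (rows preserved); attribute
#'   `chisq_p` carries the independence p-value of the returned table. A
#'   cohort whose table is already exactly proportional is returned unchanged.
#' @export
balance_filter <- function(cohort, attempts = 100, drop_empty_phase = TRUE) {
  stopifnot(is.data.frame(cohort),
            all(c("aggressiveness", "phase") %in% names(cohort)))
  g <- droplevels(as.factor(cohort$aggressiveness))
  p <- droplevels(as.factor(cohort$phase))
  tab <- table(g, p)
  empty_cols <- colnames(tab)[apply(tab == 0, 2, any)]
  if (length(empty_cols)) {
    if (!drop_empty_phase)
      stop_d50("d50als_infeasible",
               sprintf("Phase(s) %s missing from some stratum.",
                       paste(empty_cols, collapse = ", ")))
    keep <- !(p %in% empty_cols)
    cohort <- cohort[keep, , drop = FALSE]
    g <- droplevels(g[keep]); p <- droplevels(p[keep])
    tab <- table(g, p)
  }
  if (!nrow(tab) || !ncol(tab) || ncol(tab) < 1)
    stop_d50("d50als_infeasible", "No balanced subsample exists.")
  q <- colSums(tab) / sum(tab)

  # per-stratum capacity under the pooled phase proportions
  target <- function() {
    m_g <- vapply(rownames(tab), function(gg)
      floor(min(tab[gg, ] / q)), numeric(1))
    cells <- outer(m_g, q)
    round(cells)
  }
  cells <- target()
  # already exactly proportional: keep everything
  if (all(abs(cells - tab) < 0.5)) {
    attr(cohort, "chisq_p") <- suppressWarnings(
      stats::chisq.test(tab)$p.value)
    return(cohort)
  }
  best <- NULL
  for (a in seq_len(attempts)) {
    idx <- integer(0)
    for (gg in rownames(tab)) for (pp in colnames(tab)) {
      pool <- which(g == gg & p == pp)
      k <- min(cells[gg, pp], length(pool))
      if (k > 0) idx <- c(idx, sample(pool, k))
    }
    sub_tab <- table(droplevels(g[idx]), droplevels(p[idx]))
    pval <- suppressWarnings(stats::chisq.test(sub_tab)$p.value)
    if (is.na(pval)) next
    if (pval > 0.5 &&
        (is.null(best) || length(idx) > length(best$idx)))
      best <- list(idx = idx, p = pval)
  }
  if (is.null(best))
    stop_d50("d50als_infeasible",
             "No subsample passed the independence check.")
  out <- cohort[sort(best$idx), , drop = FALSE]
  attr(out, "chisq_p") <- best$p
  out
}
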