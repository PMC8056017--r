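#' Construct a D50 model fit object
#'
#' A `d50_fit` bundles the parameters of the sigmoidal functional-decline
#' model for one patient: `d50`, the months from symptom onset to halved
#' functionality (ALSFRS-R = 24); `dx`, the exponential time constant of the
#' decline in months; and `delta`, the bounded presymptomatic onset shift in
#' months (0 to 6). The model curve is anchored so that the predicted score at
#' `t = d50` is exactly 24, half of the ALSFRS-R maximum of 48.
#'
#' @param d50 Months from symptom onset to halved functionality; must be > 0.
#' @param dx Time constant of functional decline in months; must be > 0.
#' @param delta Presymptomatic onset shift in months, in \[0, 6\].
#' @param rss Residual sum of squares at the fitted parameters.
#' @param n_points Number of assessments the fit used.
#' @return An object of class `d50_fit`.
#' @examples
#' fit <- d50_fit(d50 = 20, dx = 5)
#' sigmoid_score(20, fit) # exactly 24
#' @export
d50_fit <- function(d50, dx, delta = 0, rss = NA_real_, n_points = NA_integer_) {
  if (!is_scalar_number(d50) || d50 <= 0)
    stop_d50("d50als_non_positive_d50", "`d50` must be a positive number.")
  if (!is_scalar_number(dx) || dx <= 0)
    stop_d50("d50als_non_positive_dx", "`dx` must be a positive number.")
  if (!is_scalar_number(delta) || delta < 0 || delta > 6)
    stop_d50("d50als_invalid_delta", "`delta` must lie in [0, 6] months.")
  structure(
    list(d50 = d50, dx = dx, delta = delta,
         rss = as.numeric(rss), n_points = as.integer(n_points)),
    class = "d50_fit"
  )
}

#' @export
print.d50_fit <- function(x, ...) {
  cat("D50 sigmoidal decline fit\n")
  cat(sprintf("  D50   : %.2f months (%s aggressiveness)\n",
              x$d50, aggressiveness_of(x$d50)))
  cat(sprintf("  dx    : %.2f months\n", x$dx))
  cat(sprintf("  delta : %.2f months\n", x$delta))
  if (is.finite(x$rss))
    cat(sprintf("  rss   : %.3f over %d assessments\n", x$rss, x$n_points))
  invisible(x)
}

#' Predicted ALSFRS-R score under a D50 fit
#'
#' Evaluates the sigmoidal state transition from full health (48) to complete
#' functional loss (0),
#' `N(t) = 48 / (1 + exp((t - d50) / dx))`,
#' parameterized so that `N(d50) = 24` exactly. The onset shift `delta`
#' relocates the time origin of the latent curve; because the half-functionality
#' time is reported on the observed (post-onset) scale, the shift cancels out
#' of the predicted score (see the methods vignette).
#'
#' @param t Time since reported symptom onset, months. Vectorized.
#' @param fit A [d50_fit].
#' @return Predicted ALSFRS-R score(s), strictly decreasing in `t`, in (0, 48).
#' @export
sigmoid_score <- function(t, fit) {
  stopifnot(inherits(fit, "d50_fit"))
  48 / (1 + exp((t - fit$d50) / fit$dx))
}

#' Relative D50: normalized disease course covered
#'
#' Normalizes elapsed time by the individual sigmoidal trajectory so that 0
#' marks disease onset and 0.5 the time point of halved functionality:
#' `rD50 = t / (2 * D50)`. rD50 measures how much of the disease course a
#' patient has covered, independent of how aggressive that course is.
#'
#' @param t Time since symptom onset, months (>= 0). Vectorized.
#' @param d50 Half-functionality time in months (> 0).
#' @return rD50 value(s), >= 0.
#' @export
relative_d50 <- function(t, d50) {
  if (!is.numeric(d50) || any(!is.finite(d50)) || any(d50 <= 0))
    stop_d50("d50als_non_positive_d50", "`d50` must be positive.")
  if (any(!is.finite(t)) || any(t < 0))
    stop_d50("d50als_negative_time", "`t` must be finite and >= 0.")
  t / (2 * d50)
}

#' Disease phase from rD50
#'
#' Maps rD50 to the three disease phases: the early semistable phase I
#' (0 <= rD50 < 0.25), the early progressive phase II (0.25 <= rD50 < 0.5),
#' and the late progressive and stable phase III/IV (0.5 <= rD50).
#'
#' @param rd50 rD50 value(s), >= 0.
#' @return Factor with levels `"I"`, `"II"`, `"III_IV"`.
#' @export
phase_of <- function(rd50) {
  if (!is.numeric(rd50) || any(!is.finite(rd50)) || any(rd50 < 0))
    stop_d50("d50als_negative_rd50", "`rd50` must be finite and >= 0.")
  cut(rd50, breaks = c(0, 0.25, 0.5, Inf), labels = c("I", "II", "III_IV"),
      right = FALSE, include.lowest = TRUE)
}

#' Disease aggressiveness stratum from D50
#'
#' Maps D50 to the aggressiveness strata: high (0 <= D50 < 20), intermediate
#' (20 <= D50 < 40) and low (40 <= D50) disease aggressiveness. A short time
#' to halved functionality means an aggressive course.
#'
#' @param d50 D50 value(s) in months, > 0.
#' @return Factor with levels `"high"`, `"intermediate"`, `"low"`.
#' @export
aggressiveness_of <- function(d50) {
  if (!is.numeric(d50) || any(!is.finite(d50)) || any(d50 <= 0))
    stop_d50("d50als_non_positive_d50", "`d50` must be positive.")
  cut(d50, breaks = c(0, 20, 40, Inf), labels = c("high", "intermediate", "low"),
      right = FALSE)
}

#' Linearly approximated disease progression rate
#'
#' The traditional progression metric: `(48 - ALSFRS-R at sampling) / disease
#' duration` in points lost per month.
#'
#' @param score_at_sampling ALSFRS-R total at sampling, 0 to 48.
#' @param duration_months Disease duration at sampling in months, > 0.
#' @return Progression rate in points/month.
#' @export
linear_progression_rate <- function(score_at_sampling, duration_months) {
  if (any(!is.finite(duration_months)) || any(duration_months <= 0))
    stop_d50("d50als_non_positive_duration", "`duration_months` must be > 0.")
  if (any(score_at_sampling < 0) || any(score_at_sampling > 48))
    stop_d50("d50als_invalid_score", "ALSFRS-R scores lie in [0, 48].")
  (48 - score_at_sampling) / duration_months
}

# rss of the anchored sigmoid at (d50, dx) for observed (t, score)
sigmoid_rss <- function(par, t, score) {
  pred <- 48 / (1 + exp((t - par[1]) / par[2]))
  sum((score - pred)^2)
}

#' Fit the D50 sigmoid to an ALSFRS-R time series
#'
#' Bounded nonlinear least squares for the anchored sigmoid
#' `N(t) = 48 / (1 + exp((t - d50)/dx))` on one patient's assessments.
#' Initial `d50` is the linearly interpolated time at which the score series
#' crosses 24 (or 1.5x the last observation time when it never does); a
#' five-point multistart perturbs the initial time constant by factors
#' 0.25 to 4; ties are broken by lowest rss, then lowest d50. A final
#' Levenberg-Marquardt polish sharpens the optimum. Bounds: d50 in (0, 300],
#' dx in (0, 150] months.
#'
#' @param assessments Data frame with columns `t_months` (time since symptom
#'   onset, months) and `score` (ALSFRS-R total, 0 to 48), one row per
#'   assessment; at least 2 rows at 2 distinct time points.
#' @param fix_delta Optional fixed value for the presymptomatic onset shift
#'   `delta` (months, in \[0, 6\]), recorded in the returned fit. The shift is
#'   not identifiable from scores alone (see the methods vignette) and
#'   defaults to 0.
#' @return A [d50_fit] with `rss` and `n_points` filled in.
#' @examples
#' tr <- data.frame(t_months = c(3, 9, 15, 21, 27),
#'                  score = sigmoid_score(c(3, 9, 15, 21, 27),
#'                                        d50_fit(30, 8)))
#' fit_trajectory(tr)
#' @export
fit_trajectory <- function(assessments, fix_delta = NULL) {
  stopifnot(is.data.frame(assessments),
            all(c("t_months", "score") %in% names(assessments)))
  t <- as.numeric(assessments$t_months)
  s <- as.numeric(assessments$score)
  keep <- is.finite(t) & is.finite(s)
  t <- t[keep]; s <- s[keep]
  if (any(s < 0 | s > 48))
    stop_d50("d50als_invalid_score", "ALSFRS-R scores lie in [0, 48].")
  if (length(t) < 2 || length(unique(t)) < 2)
    stop_d50("d50als_too_few_assessments",
             "At least two assessments at two distinct time points are required.")
  if (all(s >= 48))
    stop_d50("d50als_degenerate_trajectory",
             "All scores at the ALSFRS-R maximum: no decline to fit.")
  delta <- if (is.null(fix_delta)) 0 else fix_delta
  if (!is_scalar_number(delta) || delta < 0 || delta > 6)
    stop_d50("d50als_invalid_delta", "`fix_delta` must lie in [0, 6] months.")

  d50_max <- 300; dx_max <- 150
  ord <- order(t)
  t_o <- t[ord]; s_o <- s[ord]

  # initial d50: interpolated 24-crossing of the observed series
  d50_0 <- if (any(s_o <= 24)) {
    i <- which(s_o <= 24)[1]
    if (i == 1L) max(t_o[1], 1e-2)
    else t_o[i - 1] + (t_o[i] - t_o[i - 1]) * (s_o[i - 1] - 24) /
      max(s_o[i - 1] - s_o[i], 1e-8)
  } else 1.5 * max(t_o)
  d50_0 <- min(max(d50_0, 0.5), d50_max)
  dx_0 <- min(max(d50_0 / 4, 0.1), dx_max)

  best <- NULL
  for (f in c(0.25, 0.5, 1, 2, 4)) {
    start <- c(d50_0, min(max(dx_0 * f, 1e-2), dx_max))
    opt <- try(stats::optim(start, sigmoid_rss, t = t, score = s,
                            method = "L-BFGS-B",
                            lower = c(1e-3, 1e-3), upper = c(d50_max, dx_max),
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    cand <- list(par = opt$par, rss = opt$value)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 && cand$par[1] < best$par[1]))
      best <- cand
  }
  if (is.null(best))
    stop_d50("d50als_fit_failure", "Optimization failed for all starts.")

  # Levenberg-Marquardt polish from the multistart winner
  pol <- try(suppressWarnings(minpack.lm::nls.lm(
    par = best$par,
    fn = function(p) s - 48 / (1 + exp((t - p[1]) / p[2])),
    lower = c(1e-3, 1e-3), upper = c(d50_max, dx_max),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))), silent = TRUE)
  if (!inherits(pol, "try-error")) {
    prss <- sum(pol$fvec^2)
    if (prss <= best$rss + 1e-12) best <- list(par = pol$par, rss = prss)
  }

  d50_fit(d50 = best$par[1], dx = best$par[2], delta = delta,
          rss = best$rss, n_points = length(t))
}

#' Fit D50 trajectories for every patient in an assessment table
#'
#' @param assessments Data frame with columns `patient_id`, `t_months`,
#'   `alsfrs_r` (one row per assessment).
#' @param sampling_times Optional data frame with columns `patient_id` and
#'   `t_sampling_months`; when supplied, `rd50_at_sampling` and `phase` are
#'   added to the output.
#' @return Data frame with one row per fit: `patient_id`, `d50`, `dx`, `delta`,
#'   `rss`, `n_points`, `aggressiveness`, and (when sampling times are given)
#'   `rd50_at_sampling` and `phase`. Patients whose series cannot be fitted
#'   (fewer than two distinct assessments, or flat at the maximum) are dropped
#'   with a warning naming them.
#' @export
fit_cohort <- function(assessments, sampling_times = NULL) {
  stopifnot(is.data.frame(assessments),
            all(c("patient_id", "t_months", "alsfrs_r") %in% names(assessments)))
  ids <- unique(assessments$patient_id)
  rows <- vector("list", length(ids))
  dropped <- character(0)
  for (i in seq_along(ids)) {
    sub <- assessments[assessments$patient_id == ids[i], , drop = FALSE]
    fit <- tryCatch(
      fit_trajectory(data.frame(t_months = sub$t_months, score = sub$alsfrs_r)),
      d50als_error = function(e) NULL)
    if (is.null(fit)) { dropped <- c(dropped, as.character(ids[i])); next }
    rows[[i]] <- data.frame(
      patient_id = ids[i], d50 = fit$d50, dx = fit$dx, delta = fit$delta,
      rss = fit$rss, n_points = fit$n_points,
      aggressiveness = as.character(aggressiveness_of(fit$d50)),
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("Dropped unfittable patients: ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(0), d50 = numeric(0),
                      dx = numeric(0), delta = numeric(0), rss = numeric(0),
                      n_points = integer(0), aggressiveness = character(0))
  if (!is.null(sampling_times)) {
    stopifnot(all(c("patient_id", "t_sampling_months") %in% names(sampling_times)))
    m <- match(out$patient_id, sampling_times$patient_id)
    ts <- sampling_times$t_sampling_months[m]
    out$rd50_at_sampling <- ifelse(is.na(ts), NA_real_,
                                   ts / (2 * out$d50))
    out$phase <- ifelse(is.na(ts), NA_character_,
                        as.character(phase_of(pmax(out$rd50_at_sampling, 0))))
  }
  out
}

#' Linear relation between D50 and the decline time constant dx
#'
#' The two sigmoid parameters correlate linearly across patients, which is
#' what licenses using D50 alone as the aggressiveness descriptor. Returns the
#' ordinary least-squares regression of dx on D50 and their Pearson
#' correlation.
#'
#' @param fits Data frame with columns `d50` and `dx` (e.g. from
#'   [fit_cohort]), or a list of [d50_fit] objects; at least 3 fits.
#' @return List with `slope`, `intercept`, `r` (Pearson correlation).
#' @export
d50_dx_relation <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) && all(vapply(fits, inherits,
      logical(1), "d50_fit"))) {
    fits <- data.frame(d50 = vapply(fits, `[[`, numeric(1), "d50"),
                       dx = vapply(fits, `[[`, numeric(1), "dx"))
  }
  stopifnot(is.data.frame(fits), all(c("d50", "dx") %in% names(fits)))
  if (nrow(fits) < 3)
    stop_d50("d50als_too_few_fits", "At least 3 fits are required.")
  x <- fits$d50; y <- fits$dx
  co <- stats::coef(stats::lm(y ~ x))
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
  list(slope = unname(co[2]), intercept = unname(co[1]), r = r)
}
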