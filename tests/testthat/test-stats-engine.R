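test_that("rank AUC equals the all-pairs oracle, with and without ties", {
  set.seed(10)
  for (i in 1:100) {
    n1 <- sample(3:50, 1); n0 <- sample(3:50, 1)
    if (i %% 2 == 0) { # discrete draws force ties
      pos <- sample(0:8, n1, replace = TRUE) + 1
      neg <- sample(0:8, n0, replace = TRUE)
    } else {
      pos <- rnorm(n1, 0.8); neg <- rnorm(n0)
    }
    r <- roc_analysis(pos, neg)
    expect_equal(r$auc, auc_all_pairs(pos, neg), tolerance = 1e-12)
  }
})

test_that("ROC handles separation, equality, and matches pROC", {
  set.seed(11)
  sep <- roc_analysis(rnorm(40, 10), rnorm(40, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  eq <- roc_analysis(rnorm(4000), rnorm(4000))
  expect_lt(abs(eq$auc - 0.5), 0.03)

  pos <- rnorm(60, 0.7); neg <- rnorm(45)
  ours <- roc_analysis(pos, neg)
  ref <- suppressMessages(pROC::roc(
    response = c(rep(1, 60), rep(0, 45)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE))
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  # Youden cutoff achieves the maximal sensitivity + specificity - 1
  youden_at <- function(ct) mean(pos >= ct) + mean(neg < ct) - 1
  grid <- sort(c(pos, neg))
  expect_equal(youden_at(ours$optimal_cutoff), max(sapply(grid, youden_at)),
               tolerance = 1e-12)
  expect_error(roc_analysis(numeric(0), neg), class = "d50als_empty_group")
})

test_that("ANCOVA without covariates reduces to the squared t statistic", {
  set.seed(20)
  y <- c(rnorm(25, 0), rnorm(25, 0.4))
  g <- rep(c("a", "b"), each = 25)
  a <- ancova(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  i <- which(a$terms$term == "group")
  expect_equal(a$terms$F[i], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$terms$df1[i], 1)
  expect_equal(a$terms$df2[i], 48)
  # EMMs without covariates are the group means
  expect_equal(sort(a$emmeans$emmean), sort(tapply(y, g, mean)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ANCOVA recovers injected group offsets within their CIs", {
  set.seed(21)
  offsets <- c(a = 0, b = 0.2, c = 0.5)
  g <- factor(rep(names(offsets), each = 60))
  age <- rnorm(180, 63, 10)
  y <- offsets[g] + 0.005 * (age - 63) + rnorm(180, 0, 0.3)
  a <- ancova(y, g, data.frame(age = age))
  em <- a$emmeans[order(a$emmeans$level), ]
  for (lv in names(offsets)) {
    row <- em[em$level == lv, ]
    expect_true(row$lower <= offsets[[lv]] && offsets[[lv]] <= row$upper)
  }
  # Bonferroni adjustment: p_adj = min(1, raw * number of pairs), monotone
  raw <- as.data.frame(emmeans::contrast(emmeans::emmeans(a$model, ".g"),
                                         method = "pairwise",
                                         adjust = "none"))$p.value
  expect_equal(a$posthoc$p_adj, pmin(1, raw * 3), tolerance = 1e-12)
  expect_equal(order(a$posthoc$p_adj), order(raw))
})

test_that("degenerate ANCOVA designs raise classed errors", {
  y <- rnorm(20)
  expect_error(ancova(y, rep("a", 20)), class = "d50als_single_level")
  g <- rep(c("a", "b"), each = 10)
  x <- rnorm(20)
  expect_error(ancova(y, g, data.frame(x1 = x, x2 = 2 * x)),
               class = "d50als_rank_deficient")
})

test_that("correlations match closed forms and rank oracles", {
  x <- 1:20
  lin <- correlations(x, 2 * x)
  expect_equal(lin$pearson$r, 1, tolerance = 1e-12)
  expect_equal(lin$spearman$rho, 1, tolerance = 1e-12)

  mono <- correlations(x, exp(-x / 5))
  expect_equal(mono$spearman$rho, -1, tolerance = 1e-12)
  expect_gt(mono$pearson$r, -1)

  set.seed(30)
  a <- sample(1:10, 12, replace = TRUE); b <- sample(1:10, 12, replace = TRUE)
  got <- correlations(a, b)$spearman$rho
  ra <- rank(a); rb <- rank(b)
  ref <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_error(correlations(1:2, 2:3), class = "d50als_too_few_pairs")
  expect_error(correlations(rep(1, 5), 1:5), class = "d50als_zero_variance")
})

test_that("linear fit matches the normal equations", {
  exact <- linear_fit(1:10, 3 - 0.5 * (1:10))
  expect_equal(exact$slope, -0.5, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  flat <- linear_fit(1:10, rep(2, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  set.seed(31)
  x <- rnorm(25); y <- 1 + 0.3 * x + rnorm(25)
  got <- linear_fit(x, y)
  ref <- ols_normal_equations(x, y)
  expect_equal(got$slope, unname(ref["slope"]), tolerance = 1e-10)
  expect_equal(got$intercept, unname(ref["intercept"]), tolerance = 1e-10)
})

test_that("Mann-Whitney matches the exact permutation distribution", {
  dis <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(dis$U, 0)
  same <- mann_whitney(rep(1:5, 4), rep(1:5, 4))
  expect_lt(abs(same$Z), 1e-9)

  set.seed(40)
  for (i in 1:15) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    x <- rnorm(n1); y <- rnorm(n2) # continuous: tie-free
    got <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "d50als_empty_group")
})

test_that("Kaplan-Meier matches empirical survival without censoring", {
  set.seed(50)
  tm <- rexp(41, 0.1) + 0.1
  km <- kaplan_meier(tm, rep(TRUE, 41))
  expect_equal(km$median, median(tm), tolerance = 1e-9)
  expect_true(all(diff(km$curve$surv) <= 1e-12))
  expect_true(all(km$curve$surv >= 0 & km$curve$surv <= 1))
  for (j in seq_len(nrow(km$curve)))
    expect_equal(km$curve$surv[j], mean(tm > km$curve$time[j]),
                 tolerance = 1e-9)
})

test_that("log-rank equals the hand-computed quadratic form", {
  # 3-group toy table, 9 subjects, one censored
  tm <- c(1, 3, 5, 2, 4, 6, 2.5, 7, 8)
  ev <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  gr <- rep(c("a", "b", "c"), each = 3)
  got <- log_rank(tm, ev, gr)
  expect_equal(got$chisq, logrank_oracle(tm, ev, gr), tolerance = 1e-9)
  expect_equal(got$df, 2)

  # two identical groups: statistic near zero
  tm2 <- rep(c(1, 2, 3, 4), 2)
  got2 <- log_rank(tm2, rep(TRUE, 8), rep(c("a", "b"), each = 4))
  expect_lt(got2$chisq, 1e-9)
  expect_error(log_rank(1:4, rep(FALSE, 4), rep(c("a", "b"), 2)),
               class = "d50als_no_events")
})

test_that("EMM trichotomization uses the printed half-open cutoffs", {
  emms <- c(3.651, 3.857, 4.149)
  lab <- trichotomize_by_emm(emms, c(3.0, 3.651, 3.7, 4.148, 4.149, 5))
  expect_equal(as.character(lab),
               c("low", "intermediate", "intermediate", "intermediate",
                 "high", "high"))
  # partitions all finite inputs
  expect_false(anyNA(trichotomize_by_emm(emms, seq(-5, 10, by = 0.01))))
  expect_error(trichotomize_by_emm(c(4, 3, 5), 1),
               class = "d50als_unsorted_emms")
})

test_that("balance filter yields phase-homogeneous strata", {
  # already proportional: returned unchanged
  bal <- data.frame(
    aggressiveness = rep(c("high", "intermediate", "low"), each = 12),
    phase = rep(rep(c("I", "II", "III_IV"), times = c(6, 4, 2)), 3))
  out <- balance_filter(bal)
  expect_equal(nrow(out), nrow(bal))

  # skewed table: filtered table passes the independence check
  set.seed(60)
  skew <- data.frame(
    aggressiveness = rep(c("high", "intermediate", "low"),
                         times = c(43, 61, 52)),
    phase = c(sample(c("I", "II", "III_IV"), 43, TRUE, c(.26, .63, .11)),
              sample(c("I", "II", "III_IV"), 61, TRUE, c(.52, .44, .04)),
              sample(c("I", "II"), 52, TRUE, c(.64, .36))))
  flt <- balance_filter(skew)
  expect_gt(attr(flt, "chisq_p"), 0.5)
  expect_lte(nrow(flt), nrow(skew))

  # low stratum lacks phase III/IV entirely: phase dropped or infeasible
  expect_false("III_IV" %in% flt$phase[flt$aggressiveness == "low"])
  expect_error(balance_filter(skew, drop_empty_phase = FALSE),
               class = "d50als_infeasible")
})
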