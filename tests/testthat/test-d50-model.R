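test_that("sigmoid is anchored at half functionality and monotone", {
  for (p in list(c(14.56, 4), c(29.88, 8), c(62.58, 18), c(20, 5))) {
    fit <- d50_fit(p[1], p[2])
    expect_lt(abs(sigmoid_score(p[1], fit) - 24), 1e-9)
    t <- seq(0, 4 * p[1], length.out = 200)
    expect_true(all(diff(sigmoid_score(t, fit)) < 0))
    s <- sigmoid_score(t, fit)
    expect_true(all(s > 0 & s < 48))
  }
  # closed form: d50 = 20, dx = 5 at t = 25 is 48 / (1 + e)
  expect_equal(sigmoid_score(25, d50_fit(20, 5)), 48 / (1 + exp(1)),
               tolerance = 1e-12)
  # full-health plateau as t -> -inf
  expect_equal(sigmoid_score(-1e6, d50_fit(20, 5)), 48)
})

test_that("relative D50 maps onset to 0 and D50 to 0.5", {
  expect_identical(relative_d50(0, 30), 0)
  expect_identical(relative_d50(30, 30), 0.5)
  expect_identical(relative_d50(60, 30), 1)
  t <- seq(0, 100, by = 0.5)
  expect_true(all(diff(relative_d50(t, 17.3)) > 0))
  expect_error(relative_d50(5, -1), class = "d50als_non_positive_d50")
})

test_that("phase and aggressiveness strata use the printed half-open bands", {
  expect_equal(as.character(phase_of(c(0, 0.23, 0.25, 0.49, 0.5, 2))),
               c("I", "I", "II", "II", "III_IV", "III_IV"))
  expect_error(phase_of(-0.01), class = "d50als_negative_rd50")
  expect_equal(as.character(aggressiveness_of(c(14.56, 19.99, 20, 39.99, 40,
                                                62.58))),
               c("high", "high", "intermediate", "intermediate", "low", "low"))
  expect_error(aggressiveness_of(0), class = "d50als_non_positive_d50")
  # partition: every valid input maps to exactly one label
  set.seed(1)
  d <- runif(500, 0.01, 200)
  expect_false(anyNA(aggressiveness_of(d)))
  expect_false(anyNA(phase_of(runif(500, 0, 3))))
})

test_that("linear progression rate follows the printed formula", {
  expect_equal(linear_progression_rate(48, 7), 0)
  expect_equal(linear_progression_rate(36, 10), 1.2)
  expect_error(linear_progression_rate(36, 0),
               class = "d50als_non_positive_duration")
})

test_that("noiseless trajectories are recovered exactly", {
  cases <- list(c(30, 8), c(14.56, 4.2), c(62.58, 17), c(95, 30))
  for (p in cases) {
    times <- c(3, 9, 15, 21, 27) * p[1] / 30
    tr <- data.frame(t_months = times,
                     score = sigmoid_score(times, d50_fit(p[1], p[2])))
    f <- fit_trajectory(tr)
    expect_lt(abs(f$d50 - p[1]) / p[1], 1e-4)
    expect_lt(abs(f$dx - p[2]) / p[2], 1e-4)
    expect_lt(f$rss, 1e-8)
  }
})

test_that("two-point fits match the closed-form solution", {
  set.seed(42)
  for (i in 1:20) {
    t1 <- runif(1, 2, 15); t2 <- t1 + runif(1, 5, 25)
    s1 <- runif(1, 30, 46); s2 <- runif(1, 4, s1 - 5)
    ref <- two_point_sigmoid(t1, s1, t2, s2)
    if (ref["d50"] <= 0.01 || ref["d50"] > 300 || ref["dx"] > 150) next
    f <- fit_trajectory(data.frame(t_months = c(t1, t2), score = c(s1, s2)),
                        fix_delta = 0)
    expect_equal(f$d50, unname(ref["d50"]), tolerance = 1e-4)
    expect_equal(f$dx, unname(ref["dx"]), tolerance = 1e-4)
    expect_equal(f$delta, 0)
  }
})

test_that("fitted rss never exceeds the best grid-search rss", {
  set.seed(7)
  for (i in 1:5) {
    d50 <- runif(1, 8, 80); dx <- runif(1, 2, 20)
    times <- sort(runif(6, 1, 2.2 * d50))
    sc <- pmin(pmax(round(48 / (1 + exp((times - d50) / dx)) +
                            rnorm(6, 0, 2)), 0), 48)
    if (all(sc >= 48)) next
    f <- fit_trajectory(data.frame(t_months = times, score = sc))
    grid <- expand.grid(d50 = seq(1, 300, length.out = 100),
                        dx = seq(0.5, 150, length.out = 100))
    rss_grid <- vapply(seq_len(nrow(grid)), function(j) {
      pred <- 48 / (1 + exp((times - grid$d50[j]) / grid$dx[j]))
      sum((sc - pred)^2)
    }, numeric(1))
    expect_lte(f$rss, min(rss_grid) + 1e-8)
  }
})

test_that("degenerate and undersized series raise classed errors", {
  expect_error(fit_trajectory(data.frame(t_months = 3, score = 40)),
               class = "d50als_too_few_assessments")
  expect_error(fit_trajectory(data.frame(t_months = c(3, 3), score = c(40, 38))),
               class = "d50als_too_few_assessments")
  expect_error(fit_trajectory(data.frame(t_months = c(3, 9, 15),
                                         score = c(48, 48, 48))),
               class = "d50als_degenerate_trajectory")
})

test_that("D50 recovery tolerates rater noise and integer rounding", {
  set.seed(99)
  err <- replicate(40, {
    d50 <- 10^runif(1, log10(8), log10(90))
    dx <- 0.28 * d50 + rnorm(1, 0, 1.5)
    dx <- max(dx, 0.5)
    f <- simulate_and_refit(d50, dx, rater_sd = 2)
    abs(f$d50 - d50) / d50
  })
  expect_lt(median(err), 0.15)
})

test_that("D50-dx relation matches the normal-equations oracle", {
  d50 <- c(10, 20, 30, 40, 60)
  exact <- d50_dx_relation(data.frame(d50 = d50, dx = 0.25 * d50))
  expect_equal(exact$slope, 0.25, tolerance = 1e-12)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  flat <- d50_dx_relation(data.frame(d50 = d50, dx = rep(7, 5)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r, 0)
  set.seed(3)
  x <- runif(30, 5, 90); y <- 0.3 * x + rnorm(30, 0, 3)
  got <- d50_dx_relation(data.frame(d50 = x, dx = y))
  ref <- ols_normal_equations(x, y)
  expect_equal(got$slope, unname(ref["slope"]), tolerance = 1e-10)
  expect_equal(got$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  expect_error(d50_dx_relation(data.frame(d50 = 1:2, dx = 1:2)),
               class = "d50als_too_few_fits")
})
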