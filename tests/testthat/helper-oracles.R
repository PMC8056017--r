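# Independent brute-force / closed-form oracles used across test files.

# AUC as the proportion of (positive, negative) pairs with pos > neg,
# ties counted one half
auc_all_pairs <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# OLS slope/intercept from the normal equations, no lm()
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# k-group log-rank chi-square computed term by term from the risk tables
logrank_oracle <- function(times, events, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  etimes <- sort(unique(times[events]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in etimes) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    d <- sum(events & times == tt)
    ni <- vapply(levels(groups), function(g) sum(at_risk & groups == g),
                 numeric(1))
    di <- vapply(levels(groups), function(g)
      sum(events & times == tt & groups == g), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        kron <- as.numeric(i == j)
        V[i, j] <- V[i, j] +
          d * (ni[i] / n) * (kron - ni[j] / n) * (n - d) / (n - 1)
      }
    }
  }
  u <- (O - E)[-k]
  drop(t(u) %*% solve(V[-k, -k, drop = FALSE]) %*% u)
}

# two-point sigmoid through (t1,s1), (t2,s2): closed-form (d50, dx)
two_point_sigmoid <- function(t1, s1, t2, s2) {
  l1 <- log(48 / s1 - 1)
  l2 <- log(48 / s2 - 1)
  dx <- (t2 - t1) / (l2 - l1)
  c(d50 = t1 - dx * l1, dx = dx)
}

# simulate one noisy ALSFRS-R series and refit it
simulate_and_refit <- function(d50, dx, rater_sd = 2, n_visits = 5,
                               spacing = 3) {
  t0 <- max(d50 - spacing * (n_visits - 1) / 2, 0.5)
  times <- t0 + spacing * (seq_len(n_visits) - 1)
  truth <- 48 / (1 + exp((times - d50) / dx))
  obs <- pmin(pmax(round(truth + rnorm(n_visits, 0, rater_sd)), 0), 48)
  fit_trajectory(data.frame(t_months = times, score = obs))
}
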