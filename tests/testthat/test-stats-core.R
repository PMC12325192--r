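# Statistical kernel: every primitive checked against a brute-force oracle
# or an independent reference implementation.

test_that("spearman correlation handles identity, reversal and ties", {
  expect_equal(spearman_corr(1:5, 1:5)$effect, 1)
  expect_equal(spearman_corr(1:3, 3:1)$effect, -1)
  # tied data: rho equals Pearson on average ranks
  x <- c(1, 1, 2, 3); y <- c(2, 1, 4, 4)
  oracle <- cor(rank(x), rank(y))
  expect_equal(spearman_corr(x, y)$effect, oracle)
})

test_that("spearman p-values match the reference for large and small n", {
  # tied data force the reference onto the same t-approximation path
  withr::with_seed(42, {
    x <- sample(1:10, 25, replace = TRUE); y <- x + sample(1:5, 25, replace = TRUE)
  })
  s <- spearman_corr(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$effect, unname(ref$estimate))
  expect_equal(s$p_value, ref$p.value, tolerance = 1e-10)
  # tie-free data: t-approximation agrees with the exact reference closely
  # at moderate significance levels
  withr::with_seed(43, { x2 <- rnorm(25); y2 <- 0.5 * x2 + rnorm(25) })
  s2 <- spearman_corr(x2, y2)
  ref2 <- cor.test(x2, y2, method = "spearman", exact = TRUE)
  expect_equal(s2$p_value, ref2$p.value, tolerance = 0.1)
  # exact permutation path (n < 10, tie-free) against cor.test's exact p
  withr::with_seed(7, {
    for (n in c(5, 6, 7)) {
      x <- sample(n); y <- sample(n)
      s <- spearman_corr(x, y)
      ref <- cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(s$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(1, { x <- rnorm(30); y <- rnorm(30) })
  base <- spearman_corr(x, y)
  tr <- spearman_corr(exp(x), y^3 + 2 * y)
  expect_equal(tr$effect, base$effect)
  expect_equal(tr$p_value, base$p_value)
})

test_that("spearman rejects degenerate input", {
  expect_error(spearman_corr(1:2, 1:2), "3 complete pairs")
  expect_error(spearman_corr(rep(1, 5), 1:5), "zero variance")
})

test_that("rank-sum test reproduces hand-enumerated exact p-values", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  # all-ties symmetric null: U = mn/2, no evidence
  r <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$effect, 4.5)
  expect_equal(r$p_value, 1)
})

test_that("rank-sum exact p equals the enumeration reference for all tie-free inputs up to n = 10", {
  for (N in 2:10) {
    for (m in 1:(N - 1)) {
      sets <- combn(N, m)
      for (j in seq_len(ncol(sets))) {
        a <- sets[, j]; b <- setdiff(1:N, a)
        mine <- rank_sum_test(a, b)$p_value
        ref <- wilcox.test(a, b, exact = TRUE)$p.value
        expect_equal(mine, ref, tolerance = 1e-12)
      }
    }
  }
})

test_that("rank-sum normal approximation with ties matches the reference", {
  withr::with_seed(3, {
    a <- sample(1:8, 30, replace = TRUE)
    b <- sample(3:10, 25, replace = TRUE)
  })
  mine <- rank_sum_test(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE))
  expect_equal(mine$effect, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  for (alt in c("less", "greater")) {
    expect_equal(rank_sum_test(a, b, alt)$p_value,
                 suppressWarnings(wilcox.test(a, b, alternative = alt))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("rank-sum rejects empty groups", {
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(5, p <- runif(50)^2)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  # order preservation: sorted inputs give non-decreasing outputs
  q <- bh_adjust(sort(p))
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= sort(p)))
  # idempotent on flat vectors
  flat <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_adjust(flat), flat)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AUC equals the normalized U with tie handling", {
  expect_equal(auc_score(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  # complement identity without ties
  withr::with_seed(8, { s <- rnorm(40); l <- rbinom(40, 1, 0.5) })
  l[1:2] <- c(0, 1)
  expect_equal(auc_score(s, l) + auc_score(-s, l), 1)
  expect_error(auc_score(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("log-rank statistic matches a hand-computed lifetable and the reference", {
  # identical data in both groups: statistic 0
  tm <- c(1, 2, 3, 1, 2, 3); ev <- rep(1L, 6); gr <- rep(0:1, each = 3)
  expect_equal(log_rank_test(tm, ev, gr)$statistic, 0)
  # two-sample toy, hand-worked lifetable (group 1 dies at t=1,2; group 0 at 3,4):
  # t=1: n=4, n1=2, d=1 -> E += 1/2, V += (2/4)(2/4) = 1/4
  # t=2: n=3, n1=1, d=1 -> E += 1/3, V += (1/3)(2/3) = 2/9
  # t=3, t=4: no group-1 subjects at risk -> no contribution
  # O = 2, E = 5/6, V = 17/36 -> chi2 = (7/6)^2 / (17/36) = 49/17
  lr <- log_rank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(lr$statistic, 49 / 17)
  # label symmetry
  withr::with_seed(11, {
    t2 <- rexp(40); e2 <- rbinom(40, 1, 0.7); g2 <- rbinom(40, 1, 0.5)
  })
  g2[1:2] <- 0:1
  expect_equal(log_rank_test(t2, e2, g2)$statistic,
               log_rank_test(t2, e2, 1L - g2)$statistic)
  # against survival::survdiff
  ref <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(log_rank_test(t2, e2, g2)$statistic, ref$chisq, tolerance = 1e-10)
})

test_that("Cox fit matches a brute-force partial-likelihood grid search", {
  withr::with_seed(21, {
    x <- rbinom(30, 1, 0.5)
    tm <- rexp(30, 0.2 * exp(0.8 * x))
    ev <- rbinom(30, 1, 0.85)
  })
  fit <- fit_cox(matrix(x, ncol = 1), tm, ev)
  expect_true(fit$converged)
  # 1-D grid oracle: coarse scan then fine refinement
  ll <- function(b) ansdsig:::breslow_loglik(b, matrix(x - mean(x), ncol = 1), tm, ev)
  coarse <- seq(-3, 3, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, ll, 0))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  b_star <- fine[which.max(vapply(fine, ll, 0))]
  expect_equal(unname(fit$coefficients), b_star, tolerance = 1e-3)
})

test_that("Cox fit recovers null and planted effects and matches coxph", {
  withr::with_seed(31, {
    x <- rnorm(200)
    tm <- rexp(200, 0.2)          # hazard independent of x
    ev <- rbinom(200, 1, 0.8)
  })
  fit <- fit_cox(matrix(x, ncol = 1), tm, ev)
  expect_lt(abs(fit$coefficients), 0.2)
  # planted beta = 1, n = 500
  withr::with_seed(32, {
    x2 <- rnorm(500)
    tm2 <- rexp(500, 0.2 * exp(x2))
    ev2 <- rbinom(500, 1, 0.9)
  })
  fit2 <- fit_cox(matrix(x2, ncol = 1), tm2, ev2)
  expect_lt(abs(fit2$coefficients - 1), 0.15)
  ref <- survival::coxph(survival::Surv(tm2, ev2) ~ x2, ties = "breslow")
  expect_equal(unname(fit2$coefficients), unname(coef(ref)), tolerance = 1e-6)
  # multivariate agreement too
  withr::with_seed(33, {
    X <- matrix(rnorm(300 * 3), 300, 3)
    tm3 <- rexp(300, 0.2 * exp(X %*% c(0.5, -0.5, 0)))
    ev3 <- rbinom(300, 1, 0.8)
  })
  fit3 <- fit_cox(X, tm3, ev3)
  ref3 <- survival::coxph(survival::Surv(tm3, ev3) ~ X, ties = "breslow")
  expect_equal(unname(fit3$coefficients), unname(coef(ref3)), tolerance = 1e-6)
})

test_that("Cox fit flags separation and rejects zero-variance covariates", {
  # complete separation: the binary covariate perfectly orders survival
  tm <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1L, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- fit_cox(matrix(x, ncol = 1), tm, ev)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|monotone|iteration")
  expect_error(fit_cox(matrix(1, 10, 1), rexp(10), rep(1L, 10)), "zero-variance")
})
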