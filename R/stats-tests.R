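# Self-contained statistical kernel: every downstream stage calls these
# rather than dispatching to modelling packages, so that each primitive has a
# brute-force oracle in the test suite and identical tie/missing-value
# conventions across the pipeline.

new_test_result <- function(statistic, p_value, effect, n, method,
                            alternative = "two.sided") {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         effect = unname(effect), n = as.integer(n), method = method,
         alternative = alternative),
    class = "ansd_test")
}

#' @export
print.ansd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, effect = %.6g, p = %.4g (n = %d, %s)\n",
              x$method, x$statistic, x$effect, x$p_value, x$n, x$alternative))
  invisible(x)
}

all_permutations <- function(n) {
  # n! x n matrix of all permutations of 1..n (n <= 9 in practice)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Pairs with missing values are removed. The correlation is the Pearson
#' correlation of midranks. For `n >= 10` the p-value uses the t
#' approximation with `n - 2` degrees of freedom; for smaller samples the
#' exact permutation distribution of rho is enumerated.
#'
#' @param x,y Numeric vectors of equal length.
#' @return An object of class `ansd_test` with `effect` = rho.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_ansd("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_ansd("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ansd("zero variance in x or y: correlation undefined")
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    stat <- tt
  } else {
    # exact permutation distribution of rho given the observed rank vectors
    perms <- all_permutations(n)
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rhos <- (matrix(cy[perms], nrow(perms), n) %*% cx) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    stat <- rho
  }
  new_test_result(stat, min(p, 1), rho, n, "spearman")
}

rank_sum_u <- function(a, b) {
  r <- avg_rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Exact p-value by enumeration of all `choose(m + n, m)` group assignments
#' when the pooled sample size is at most 12 and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (the two groups); `effect` is the U statistic
#'   for `a`.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`.
#' @return An object of class `ansd_test`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) stop_ansd("both groups must be non-empty")
  u <- rank_sum_u(a, b)
  N <- m + n
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  if (N <= 12L && !ties) {
    idx <- utils::combn(N, m)
    r <- avg_rank(pooled)
    us <- colSums(matrix(r[idx], m, ncol(idx))) - m * (m + 1) / 2
    p_le <- mean(us <= u + 1e-9)
    p_ge <- mean(us >= u - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    stat <- u
  } else {
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    v <- m * n / 12 * ((N + 1) - tie_term)
    mu <- m * n / 2
    if (v <= 0) {
      stat <- 0; p <- 1
    } else {
      cc <- 0.5
      z <- switch(alternative,
                  two.sided = (u - mu - sign(u - mu) * cc) / sqrt(v),
                  greater = (u - mu - cc) / sqrt(v),
                  less = (u - mu + cc) / sqrt(v))
      p <- switch(alternative,
                  two.sided = 2 * stats::pnorm(-abs(z)),
                  greater = stats::pnorm(z, lower.tail = FALSE),
                  less = stats::pnorm(z))
      stat <- z
    }
  }
  res <- new_test_result(stat, min(p, 1), u, N, "rank_sum", alternative)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_ansd("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0L) return(q)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
  q
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U of positive-class scores versus
#' negative-class scores; tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores (higher = more positive-like).
#' @param labels Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- check_binary(labels)
  keep <- is.finite(scores)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop_ansd("both classes must be present")
  r <- avg_rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled distinct event
#' times with hypergeometric variance; chi-square with 1 df.
#'
#' @param time Positive follow-up times.
#' @param event Binary event indicator (1 = event, 0 = censored).
#' @param group Binary group indicator.
#' @return An object of class `ansd_test`; `statistic` is the chi-square.
#' @export
log_rank_test <- function(time, event, group) {
  event <- check_binary(event, "event")
  group <- check_binary(group, "group")
  keep <- is.finite(time)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  if (any(time <= 0)) stop_ansd("times must be positive")
  if (length(unique(group)) < 2L) stop_ansd("both groups must be non-empty")
  dt <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d_t <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & group == 1L)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  new_test_result(chisq, p, O - E, length(time), "log_rank")
}
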