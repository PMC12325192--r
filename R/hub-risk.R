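# Consensus feature selection (>= 3 of 5 selectors) for the hub signature,
# Cox-coefficient risk scoring, maximally selected cut-point, and KM
# reporting. The consensus RULE is the contract here; the "Bayesian" and
# "LQV" selectors of the original description are under-specified and are
# instantiated as a Gaussian evidence filter and a per-feature AUC filter
# with pluggable interfaces.

boruta_select <- function(x, y, n_iter = 50L, ntree = 300L, p_confirm = 0.01) {
  p <- ncol(x)
  hits <- integer(p)
  yf <- factor(y, levels = c(0, 1))
  for (it in seq_len(n_iter)) {
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0(".shadow", seq_len(p))
    rf <- randomForest::randomForest(cbind(x, shadow), yf, ntree = ntree,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    thr <- max(imp[paste0(".shadow", seq_len(p))])
    hits <- hits + as.integer(imp[colnames(x)] > thr)
  }
  pv <- stats::pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  selected <- colnames(x)[pv < p_confirm]
  list(selected = selected, score = stats::setNames(hits / n_iter, colnames(x)))
}

rf_importance_select <- function(x, y, ntree = 500L) {
  rf <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  list(selected = names(imp)[imp > 0], score = imp)
}

bagged_trees_select <- function(x, y, ntree = 200L) {
  # bagging = random forest with mtry = p; impurity (Gini) importance
  rf <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = ntree, mtry = ncol(x))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  list(selected = names(imp)[imp > mean(imp)], score = imp)
}

bayes_filter_select <- function(x, y, q_cut = 0.05) {
  # per-feature Gaussian likelihood-ratio of class-conditional vs pooled
  # model; chi-square with 2 df (mean and variance freed per class), BH
  stats_per <- apply(x, 2, function(v) {
    ll_class <- sum(vapply(c(0L, 1L), function(cl) {
      vc <- v[y == cl]
      sum(stats::dnorm(vc, mean(vc), max(stats::sd(vc), 1e-8), log = TRUE))
    }, 0))
    ll_pool <- sum(stats::dnorm(v, mean(v), max(stats::sd(v), 1e-8), log = TRUE))
    2 * (ll_class - ll_pool)
  })
  pv <- stats::pchisq(pmax(stats_per, 0), df = 2, lower.tail = FALSE)
  qv <- bh_adjust(pv)
  list(selected = colnames(x)[qv < q_cut], score = stats_per)
}

auc_filter_select <- function(x, y, auc_cut = 0.6) {
  sc <- apply(x, 2, function(v) {
    a <- auc_score(v, y)
    max(a, 1 - a)  # direction-free discriminability
  })
  list(selected = names(sc)[sc >= auc_cut], score = sc)
}

#' Run the five feature selectors
#'
#' Selectors (seeded, in order): `boruta` (shadow-feature permutation + RF
#' permutation importance with binomial confirmation), `rf_importance`
#' (permutation importance > 0), `bagged_trees` (bagging impurity importance
#' above the mean), `bayes_filter` (per-feature class-conditional Gaussian
#' log-evidence ratio, BH-significant), `lvq_filter` (per-feature AUC >=
#' 0.6). Constant features are excluded with a warning.
#'
#' @param x Matrix, samples x features.
#' @param y Binary 0/1 target (response labels by default in this pipeline;
#'   any binary target works).
#' @param seed Integer seed.
#' @param boruta_iter Boruta iterations (<= 100).
#' @return Named list of selector results, each with `selected` and `score`.
#' @export
run_selectors <- function(x, y, seed = 1L, boruta_iter = 50L) {
  x <- as.matrix(x)
  y <- check_binary(y, "y")
  if (ncol(x) < 2L) stop_ansd("need >= 2 features")
  if (length(unique(y)) < 2L) stop_ansd("both classes must be present")
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("excluding constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  list(
    boruta = with_seed(seed + 1L, boruta_select(x, y, n_iter = boruta_iter)),
    rf_importance = with_seed(seed + 2L, rf_importance_select(x, y)),
    bagged_trees = with_seed(seed + 3L, bagged_trees_select(x, y)),
    bayes_filter = bayes_filter_select(x, y),
    lvq_filter = auc_filter_select(x, y)
  )
}

#' Consensus hub set from selector votes
#'
#' @param results Output of [run_selectors()] (or any named list with
#'   `selected` elements).
#' @param min_votes Minimum number of selectors that must pick a gene (3).
#' @return List with `hub` (sorted gene vector) and `votes` (data frame
#'   gene x per-selector logical + vote count).
#' @export
consensus_hub <- function(results, min_votes = 3L) {
  if (length(results) < min_votes) {
    stop_ansd("fewer selectors (", length(results), ") than min_votes (", min_votes, ")")
  }
  genes <- sort(unique(unlist(lapply(results, `[[`, "selected"))))
  votes <- vapply(results, function(r) genes %in% r$selected,
                  logical(length(genes)))
  votes <- matrix(votes, nrow = length(genes),
                  dimnames = list(genes, names(results)))
  count <- rowSums(votes)
  list(hub = genes[count >= min_votes],
       votes = data.frame(gene = genes, votes, count = count,
                          row.names = NULL, check.names = FALSE))
}

#' Fit the Cox risk model on hub genes
#'
#' Multivariate Cox coefficients via [fit_cox()]; the per-sample RiskScore is
#' the linear form `sum_g beta_g * expr[g, s]`.
#'
#' @param expr Expression matrix, genes x samples (hub genes).
#' @param os_time,os_event Survival outcome.
#' @return List of class `risk_model`: `beta`, `scores`, `cox`.
#' @export
fit_risk_model <- function(expr, os_time, os_event) {
  X <- t(as.matrix(expr))
  fit <- fit_cox(X, os_time, os_event)
  if (!fit$converged) {
    stop_ansd("Cox fit did not converge (", fit$diagnostic %||% "unknown",
              "); consider reducing the gene set or a ridge fallback")
  }
  scores <- drop(X %*% fit$coefficients)
  structure(list(beta = fit$coefficients,
                 scores = stats::setNames(scores, colnames(expr)),
                 cox = fit),
            class = "risk_model")
}

#' Maximally selected survival cut-point
#'
#' Scans the distinct observed score values inside the
#' `[min_group_fraction, 1 - min_group_fraction]` quantile band and picks the
#' cutoff maximizing the two-group log-rank chi-square; ties resolve to the
#' lower cutoff. Samples with score strictly above the cutoff are "high".
#'
#' @param scores Numeric risk scores.
#' @param os_time,os_event Survival outcome.
#' @param min_group_fraction Minimum fraction of samples per group (0.1).
#' @return List: `cutoff`, `groups` (factor high/low), `statistic`,
#'   `p_value`.
#' @export
optimal_cutoff <- function(scores, os_time, os_event, min_group_fraction = 0.1) {
  n <- length(scores)
  if (n < 10L) stop_ansd("need >= 10 samples")
  if (sum(os_event) < 2L) stop_ansd("need >= 2 events")
  if (stats::sd(scores) == 0) stop_ansd("constant scores: no cut-point exists")
  qs <- stats::quantile(scores, c(min_group_fraction, 1 - min_group_fraction))
  cand <- sort(unique(scores))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  min_n <- ceiling(min_group_fraction * n)
  best <- NULL
  for (cut in cand) {
    hi <- scores > cut
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    st <- log_rank_test(os_time, os_event, as.integer(hi))$statistic
    if (is.null(best) || st > best$stat + 1e-12) best <- list(cut = cut, stat = st)
  }
  if (is.null(best)) stop_ansd("no admissible cut-point under the group-size constraint")
  groups <- factor(ifelse(scores > best$cut, "high", "low"),
                   levels = c("low", "high"))
  lr <- log_rank_test(os_time, os_event, as.integer(groups == "high"))
  list(cutoff = best$cut, groups = groups, statistic = lr$statistic,
       p_value = lr$p_value)
}

#' Kaplan-Meier curves and log-rank test for risk groups
#'
#' Product-limit estimates per group (via survival::survfit) and the
#' log-rank test from the statistical kernel.
#'
#' @param groups Factor/character group labels (two non-empty groups).
#' @param os_time,os_event Survival outcome.
#' @return List: `curves` (data frame group, time, n_risk, n_event, surv)
#'   and `test` (`ansd_test`).
#' @export
km_report <- function(groups, os_time, os_event) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L) stop_ansd("need exactly two non-empty groups")
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ groups)
  grp <- rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv)
  test <- log_rank_test(os_time, os_event,
                        as.integer(groups == levels(groups)[2]))
  list(curves = curves, test = test)
}
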