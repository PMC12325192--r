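# Single-sample gene-set enrichment (ssGSEA). Per unit, genes are ranked by
# expression; the enrichment score is the summed difference between the
# rank-weighted in-set ECDF and the uniform out-of-set ECDF. The kcdf
# parameter of the common bulk implementation is inert for this method and
# recorded only for provenance.

#' Single-sample gene-set enrichment scores
#'
#' For each unit (cell or sample), genes are sorted by decreasing expression
#' with ties broken by gene name (lexicographic), giving deterministic,
#' platform-independent output. With `N` genes, the gene at sorted position
#' `i` carries rank weight `(N - i + 1)^alpha` when it belongs to the set.
#' The enrichment score is
#' `ES = sum_i [ P_in^w(i) - P_out(i) ]`
#' where `P_in^w` is the weighted cumulative fraction of in-set genes and
#' `P_out` the cumulative fraction of out-of-set genes. With
#' `normalize = TRUE` all scores are divided by the global `max - min` over
#' the whole score matrix, so normalized scores are comparable only within
#' one call.
#'
#' @param expr Numeric expression matrix, genes x units (>= 2 genes).
#' @param sets Named list of gene-symbol vectors (or a single character
#'   vector, treated as one set).
#' @param alpha Rank-weighting exponent (0.75, the conventional default).
#' @param normalize Divide by the global score range.
#' @param kcdf Recorded but unused for this method; kept for interface
#'   compatibility.
#' @return Numeric matrix, sets x units, with attribute `"normalized"`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.75, normalize = TRUE,
                          kcdf = "Gaussian") {
  if (is.character(sets)) sets <- list(set = sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_ansd("gene sets must be named")
  }
  expr <- as.matrix(expr)
  N <- nrow(expr)
  if (N < 2L) stop_ansd("expression matrix must have at least 2 genes")
  genes <- rownames(expr)
  sets_use <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    present <- intersect(members, genes)
    if (length(present) == 0L) {
      stop_ansd(sprintf("gene set '%s' has no members in the expression matrix", nm))
    }
    if (length(present) < length(members)) {
      warning(sprintf("gene set '%s': dropping %d member(s) absent from the matrix",
                      nm, length(members) - length(present)), call. = FALSE)
    }
    present
  })
  names(sets_use) <- names(sets)
  n_units <- ncol(expr)
  scores <- matrix(NA_real_, length(sets_use), n_units,
                   dimnames = list(names(sets_use), colnames(expr)))
  # order genes lexicographically once so that order(-x, gene_idx) breaks
  # expression ties by gene name
  lex <- order(genes)
  lex_rank <- order(lex)
  w_all <- (N:1)^alpha
  for (j in seq_len(n_units)) {
    x <- expr[, j]
    ord <- order(-x, lex_rank)   # descending value, then gene name
    for (k in seq_along(sets_use)) {
      ind <- genes[ord] %in% sets_use[[k]]
      w <- w_all * ind
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ind) / (N - sum(ind))
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "normalized") <- normalize
  attr(scores, "kcdf") <- kcdf
  scores
}

#' Compare one score row across groups
#'
#' All pairwise two-sided rank-sum tests with Benjamini-Hochberg adjustment
#' across the pairs.
#'
#' @param scores Numeric vector of per-unit scores.
#' @param groups Factor/character vector of group labels, same length.
#' @return Data frame: group1, group2, n1, n2, U, p_value, q_value.
#' @export
score_groups <- function(scores, groups) {
  groups <- as.character(groups)
  stopifnot(length(scores) == length(groups))
  keep <- is.finite(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- groups[keep]
  lv <- sort(unique(groups))
  if (length(lv) < 2L) stop_ansd("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_ansd("each group needs >= 2 units; offending: ",
              paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- scores[groups == pr[1]]; b <- scores[groups == pr[2]]
    tt <- rank_sum_test(a, b)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a), n2 = length(b),
               U = tt$effect, p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}
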