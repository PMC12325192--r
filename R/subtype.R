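# Consensus clustering for molecular subtyping, subtype-level score
# comparisons, mutation-frequency summaries, and the score-infiltration
# correlation filter.

#' Consensus clustering configuration
#'
#' @param k_range Candidate cluster numbers (2:6).
#' @param repetitions Subsampling repetitions (1000).
#' @param subsample_fraction Fraction of samples drawn per repetition (0.8).
#' @param seed Integer seed.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(k_range = 2:6, repetitions = 1000L,
                             subsample_fraction = 0.8, seed = 1L) {
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop_ansd("subsample_fraction must be in (0, 1)")
  }
  if (any(k_range < 2L)) stop_ansd("k_range must be >= 2")
  if (repetitions < 10L) warning("fewer than 10 repetitions: consensus will be noisy",
                                 call. = FALSE)
  structure(list(k_range = as.integer(k_range),
                 repetitions = as.integer(repetitions),
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[i, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Subsampled consensus clustering
#'
#' For each k: repeatedly subsample `subsample_fraction` of the samples,
#' k-means (Euclidean, k-means++ initialization) on the subsample, and
#' accumulate co-clustering counts. The consensus matrix is
#' `M_ij = co-clustered_ij / co-sampled_ij`. Final assignments come from an
#' average-linkage hierarchical cut of `1 - M` into k groups. k is chosen by
#' the largest relative delta-area of the consensus CDF; PAC (proportion of
#' ambiguous clustering in the 0.1-0.9 band) is reported alongside.
#'
#' @param expr Expression matrix, features (e.g. hub genes) x samples;
#'   samples are clustered.
#' @param config A [consensus_config()].
#' @return List of class `consensus_result`: `consensus` (per-k matrices),
#'   `cdf` (per-k data frames), `area`, `delta_area`, `pac`, `chosen_k`,
#'   `assignments` (per-k integer vectors), `best_assignment`.
#' @export
consensus_cluster <- function(expr, config = consensus_config()) {
  x <- t(as.matrix(expr))  # samples x features
  n <- nrow(x)
  if (n < 10L) stop_ansd("need >= 10 samples")
  if (sum(apply(x, 2, stats::sd)) == 0) {
    stop_ansd("degenerate input: all samples identical")
  }
  m_sub <- ceiling(config$subsample_fraction * n)
  if (any(config$k_range > m_sub)) stop_ansd("k exceeds the subsample size")
  ids <- rownames(x) %||% as.character(seq_len(n))
  consensus <- list(); assignments <- list()
  cdfs <- list(); area <- numeric(0); pac <- numeric(0)
  grid <- seq(0, 1, by = 0.01)
  for (k in config$k_range) {
    conn <- matrix(0, n, n)
    samp <- matrix(0, n, n)
    with_seed(config$seed + k, {
      for (r in seq_len(config$repetitions)) {
        sub <- sample.int(n, m_sub)
        km <- stats::kmeans(x[sub, , drop = FALSE],
                            centers = kmeanspp_centers(x[sub, , drop = FALSE], k),
                            iter.max = 50L)
        samp[sub, sub] <- samp[sub, sub] + 1
        for (cl in seq_len(k)) {
          mem <- sub[km$cluster == cl]
          conn[mem, mem] <- conn[mem, mem] + 1
        }
      }
    })
    M <- ifelse(samp > 0, conn / pmax(samp, 1), 0)
    d <- diag(M); d[diag(samp) > 0] <- 1; diag(M) <- d
    dimnames(M) <- list(ids, ids)
    consensus[[as.character(k)]] <- M
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    assignments[[as.character(k)]] <- stats::setNames(stats::cutree(hc, k), ids)
    v <- M[upper.tri(M)]
    cdf <- vapply(grid, function(g) mean(v <= g), 0)
    cdfs[[as.character(k)]] <- data.frame(consensus = grid, cdf = cdf)
    area[as.character(k)] <- sum(diff(grid) * cdf[-1])
    pac[as.character(k)] <- mean(v > 0.1 & v <= 0.9)
  }
  ks <- as.character(config$k_range)
  delta <- c(area[ks[1]],
             if (length(ks) > 1) diff(area[ks]) / utils::head(area[ks], -1))
  names(delta) <- ks
  chosen <- as.integer(names(which.max(delta)))
  structure(list(consensus = consensus, cdf = cdfs, area = area,
                 delta_area = delta, pac = pac, chosen_k = chosen,
                 assignments = assignments,
                 best_assignment = assignments[[as.character(chosen)]]),
            class = "consensus_result")
}

#' Compare sample-level scores between subtypes
#'
#' With two clusters, a two-sided rank-sum test per score column with BH
#' across scores; with more clusters, all pairwise tests (flagged) with BH
#' across every (score, pair).
#'
#' @param assignments Cluster labels per sample (named or aligned).
#' @param scores Data frame / matrix of sample-level scores (samples x
#'   scores), e.g. dysfunction, TMB, MSI.
#' @return Data frame: score, group1, group2, U, p_value, q_value.
#' @export
compare_subtype_scores <- function(assignments, scores) {
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == length(assignments))
  cl <- as.character(assignments)
  lv <- sort(unique(cl))
  if (length(lv) < 2L) stop_ansd("need >= 2 clusters")
  if (length(lv) > 2L) {
    message("more than 2 clusters: reporting all pairwise comparisons")
  }
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (sc in names(scores)) {
    v <- scores[[sc]]
    miss <- sum(is.na(v))
    if (miss > 0) message(sprintf("compare_subtype_scores: '%s': dropping %d missing value(s)", sc, miss))
    for (j in seq_len(ncol(pairs))) {
      a <- v[cl == pairs[1, j] & !is.na(v)]
      b <- v[cl == pairs[2, j] & !is.na(v)]
      if (length(a) < 2L || length(b) < 2L) {
        stop_ansd("cluster with < 2 usable samples for score '", sc, "'")
      }
      tt <- rank_sum_test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        score = sc, group1 = pairs[1, j], group2 = pairs[2, j],
        U = tt$effect, p_value = tt$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Per-cluster gene mutation frequencies from a MAF-like table
#'
#' A sample counts at most once per gene regardless of how many variant rows
#' it has. Variant classes in `exclude_classes` (Silent by default) are
#' ignored. MAF rows whose sample is not in `assignments` are dropped with a
#' logged count.
#'
#' @param maf Data frame with `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification`.
#' @param assignments Named cluster vector (names = sample barcodes).
#' @param exclude_classes Variant classes that do not count as mutated.
#' @return Data frame: gene, cluster, mutated_samples, cluster_size,
#'   frequency; sorted by cluster then decreasing frequency.
#' @export
mutation_frequency <- function(maf, assignments,
                               exclude_classes = "Silent") {
  stopifnot(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification") %in% names(maf)))
  if (nrow(maf) == 0L) stop_ansd("empty MAF table")
  maf <- maf[!(maf$Variant_Classification %in% exclude_classes), , drop = FALSE]
  mapped <- maf$Tumor_Sample_Barcode %in% names(assignments)
  if (any(!mapped)) {
    message(sprintf("mutation_frequency: dropping %d row(s) with unmapped samples",
                    sum(!mapped)))
    maf <- maf[mapped, , drop = FALSE]
  }
  maf <- maf[!duplicated(maf[c("Hugo_Symbol", "Tumor_Sample_Barcode")]), ,
             drop = FALSE]
  cl_sizes <- table(assignments)
  maf$cluster <- assignments[maf$Tumor_Sample_Barcode]
  tab <- table(maf$Hugo_Symbol, maf$cluster)
  rows <- list()
  for (cl in names(cl_sizes)) {
    cnt <- if (cl %in% colnames(tab)) tab[, cl] else
      stats::setNames(rep(0L, nrow(tab)), rownames(tab))
    rows[[cl]] <- data.frame(gene = rownames(tab), cluster = cl,
                             mutated_samples = as.integer(cnt),
                             cluster_size = as.integer(cl_sizes[cl]),
                             frequency = as.numeric(cnt) / as.integer(cl_sizes[cl]),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster, -out$frequency, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Score-covariate Spearman correlations with a significance filter
#'
#' Spearman correlation of each feature row against each covariate row over
#' the shared samples; pairs with `p < p_cut` are kept, sorted by decreasing
#' absolute rho, with the strongest positive and negative pairs flagged.
#'
#' @param features Named numeric vector (one score) or matrix (features x
#'   samples).
#' @param covariates Matrix/data frame, covariates x samples (e.g.
#'   infiltration abundances).
#' @param p_cut Retention threshold on the raw p-value (0.05).
#' @return Data frame: feature, covariate, rho, p_value, flag
#'   ("top_positive"/"top_negative"/"").
#' @export
correlate_with_covariates <- function(features, covariates, p_cut = 0.05) {
  if (is.null(dim(features))) {
    features <- matrix(features, 1, dimnames = list("score", names(features)))
  }
  covariates <- as.matrix(covariates)
  shared <- intersect(colnames(features), colnames(covariates))
  if (length(shared) < 3L) stop_ansd("fewer than 3 shared samples")
  rows <- list()
  for (f in rownames(features)) {
    for (cv in rownames(covariates)) {
      tt <- spearman_corr(features[f, shared], covariates[cv, shared])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, covariate = cv, rho = tt$effect, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$p_value < p_cut, , drop = FALSE]
  out <- out[order(-abs(out$rho)), , drop = FALSE]
  out$flag <- ""
  if (any(out$rho > 0)) out$flag[which.max(out$rho)] <- "top_positive"
  if (any(out$rho < 0)) out$flag[which.min(out$rho)] <- "top_negative"
  rownames(out) <- NULL
  out
}
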