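# Cross-screen CRISPR integration: standardize logFC within each dataset,
# average the z-scores per gene over the datasets where it is observed, rank
# ascending (low mean z = resistance-like), and summarize signature
# membership in top fractions.

#' Standardize CRISPR logFC tables to z-scores
#'
#' Default (`mode = "within_dataset"`): for dataset `d`,
#' `z(g, d) = (logFC(g, d) - mu_d) / sigma_d` where `mu_d`, `sigma_d` are the
#' mean and SD of logFC across the genes of that dataset - this removes
#' per-screen location/scale batch effects and makes screens comparable.
#' `mode = "per_gene"` is the literal per-gene standardization across
#' datasets; it is degenerate for ranking (every gene's mean z is zero) and
#' is kept only for audit.
#'
#' @param screens Either a long data.frame (columns gene, dataset, logfc) or
#'   a named list of named per-dataset logFC vectors.
#' @param mode `"within_dataset"` (default) or `"per_gene"`.
#' @return A list of class `zscore_table`: `z` (genes x datasets, NA =
#'   missing), `mean_z`, `n_datasets_observed`.
#' @export
zscore_normalize <- function(screens, mode = c("within_dataset", "per_gene")) {
  mode <- match.arg(mode)
  if (is.data.frame(screens)) {
    stopifnot(all(c("gene", "dataset", "logfc") %in% names(screens)))
    screens <- split(stats::setNames(screens$logfc, screens$gene), screens$dataset)
  }
  if (length(screens) < 2L) stop_ansd("need >= 2 datasets")
  genes <- sort(unique(unlist(lapply(screens, names))))
  z <- matrix(NA_real_, length(genes), length(screens),
              dimnames = list(genes, names(screens)))
  for (d in names(screens)) {
    x <- screens[[d]]
    if (length(x) < 2L) stop_ansd("dataset '", d, "' has fewer than 2 genes")
    z[names(x), d] <- x
  }
  if (mode == "within_dataset") {
    for (d in colnames(z)) {
      v <- z[, d]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) stop_ansd("dataset '", d, "' has zero logFC spread")
      z[, d] <- (v - mean(v, na.rm = TRUE)) / s
    }
  } else {
    for (g in seq_len(nrow(z))) {
      v <- z[g, ]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) next
      z[g, ] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  n_obs <- rowSums(!is.na(z))
  structure(list(z = z, mean_z = rowMeans(z, na.rm = TRUE),
                 n_datasets_observed = n_obs),
            class = "zscore_table")
}

#' Rank genes by mean z-score
#'
#' Ascending mean z: rank 1 is the most resistance-like gene (knockdown most
#' consistently favoured immune attack). Ties are broken by gene name.
#'
#' @param table A [zscore_normalize()] result.
#' @param min_datasets Minimum number of datasets a gene must be observed in.
#' @return Data frame (gene, mean_z, n_datasets_observed, rank) sorted by
#'   rank.
#' @export
rank_by_mean_z <- function(table, min_datasets = 1L) {
  stopifnot(inherits(table, "zscore_table"), min_datasets >= 1L)
  keep <- table$n_datasets_observed >= min_datasets
  if (!any(keep)) stop_ansd("no gene observed in >= ", min_datasets, " datasets")
  df <- data.frame(gene = names(table$mean_z)[keep],
                   mean_z = unname(table$mean_z[keep]),
                   n_datasets_observed = unname(table$n_datasets_observed[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$mean_z, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Signature membership in top-ranked fractions
#'
#' For each fraction f, the top list holds the first `floor(f * n_ranked)`
#' genes; membership is counted over the query genes present in the ranked
#' universe, and the percentage is relative to that in-universe query size.
#'
#' @param ranked A [rank_by_mean_z()] data frame.
#' @param fractions Numeric fractions in (0, 1].
#' @param query_set Character vector of query genes (e.g. a signature).
#' @return Data frame: fraction, top_size, members_in_top, query_in_universe,
#'   percentage.
#' @export
top_fraction_stats <- function(ranked, fractions, query_set) {
  stopifnot(all(fractions > 0 & fractions <= 1), length(query_set) >= 1L)
  query <- intersect(unique(query_set), ranked$gene)
  if (length(query) == 0L) stop_ansd("query set entirely absent from the ranked universe")
  n <- nrow(ranked)
  out <- lapply(fractions, function(f) {
    top_size <- floor(f * n)
    top <- ranked$gene[seq_len(top_size)]
    hit <- sum(query %in% top)
    data.frame(fraction = f, top_size = top_size, members_in_top = hit,
               query_in_universe = length(query),
               percentage = hit / length(query))
  })
  do.call(rbind, out)
}
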