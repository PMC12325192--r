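# Multi-dataset CRISPR screen generator: per-dataset logFC tables with
# dataset-specific location/scale, planted resistance genes shifted negative,
# and missing-at-random entries.

#' Configuration for synthetic CRISPR knockout screens
#'
#' Defaults mirror the integration this package targets: 17 datasets over a
#' 22,505-gene universe.
#'
#' @param n_genes Gene-universe size.
#' @param n_datasets Number of screens (>= 2).
#' @param resistance_genes Planted resistance genes (default: the first 50
#'   universe genes).
#' @param shift Negative logFC shift applied to planted genes in every
#'   dataset where they are observed.
#' @param missing_rate Per-(gene, dataset) dropout probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `crispr_config`.
#' @export
crispr_config <- function(n_genes = 22505L, n_datasets = 17L,
                          resistance_genes = NULL, shift = -3,
                          missing_rate = 0.1, seed = 1L) {
  if (n_datasets < 2L) stop_ansd("need >= 2 datasets for z-score integration")
  if (shift >= 0) stop_ansd("resistance shift must be negative")
  if (missing_rate < 0 || missing_rate >= 1) stop_ansd("missing_rate must be in [0, 1)")
  structure(as.list(environment()), class = "crispr_config")
}

#' Generate synthetic CRISPR screen logFC tables
#'
#' Background logFC is `N(loc_d, scale_d^2)` with dataset-specific location
#' (`N(0, 0.5)`) and scale (`U(0.8, 1.2)`); planted resistance genes receive
#' the negative `shift` wherever observed. Entries are dropped independently
#' at `missing_rate`.
#'
#' @param config A [crispr_config()].
#' @return List with `table` (long data.frame: gene, dataset, logfc),
#'   `screens` (list of named per-dataset logFC vectors) and `truth`.
#' @export
make_crispr_screens <- function(config) {
  stopifnot(inherits(config, "crispr_config"))
  genes <- gene_universe(config$n_genes)
  resistance <- config$resistance_genes %||% genes[seq_len(min(50L, config$n_genes))]
  bad <- setdiff(resistance, genes)
  if (length(bad)) stop_ansd("planted genes outside universe: ", paste(bad, collapse = ", "))
  with_seed(config$seed, {
    ds_ids <- sprintf("D%02d", seq_len(config$n_datasets))
    loc <- stats::rnorm(config$n_datasets, 0, 0.5)
    scl <- stats::runif(config$n_datasets, 0.8, 1.2)
    screens <- vector("list", config$n_datasets)
    names(screens) <- ds_ids
    is_res <- genes %in% resistance
    for (d in seq_len(config$n_datasets)) {
      lfc <- stats::rnorm(config$n_genes, loc[d], scl[d])
      lfc[is_res] <- lfc[is_res] + config$shift
      keep <- stats::runif(config$n_genes) >= config$missing_rate
      # a screen must retain at least 2 genes; planted genes stay observed in
      # at least one dataset by construction of the default missing rate
      if (sum(keep) < 2L) keep[1:2] <- TRUE
      screens[[d]] <- stats::setNames(lfc[keep], genes[keep])
    }
    table <- do.call(rbind, lapply(ds_ids, function(d) {
      data.frame(gene = names(screens[[d]]), dataset = d,
                 logfc = unname(screens[[d]]), stringsAsFactors = FALSE)
    }))
    truth <- list(resistance_genes = resistance, shift = config$shift,
                  dataset_location = stats::setNames(loc, ds_ids),
                  dataset_scale = stats::setNames(scl, ds_ids),
                  config = config)
    list(table = table, screens = screens, truth = truth)
  })
}
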