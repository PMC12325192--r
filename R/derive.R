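# Signature derivation: per-dataset QC -> normalization -> malignant-vs-rest
# differential expression (Gy) and program-score correlation (Gx), their
# intersection (Gn), and the cross-dataset union that forms the signature.

#' Quality-control parameters for cell filtering
#'
#' @param min_detected_genes Cells detecting fewer genes are removed
#'   (default 300, i.e. "less than 300" fails).
#' @param max_mito_fraction Cells with a strictly larger mitochondrial read
#'   fraction are removed (default 0.20; exactly 20% is kept).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_detected_genes = 300L, max_mito_fraction = 0.20) {
  if (min_detected_genes < 0) stop_ansd("min_detected_genes must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop_ansd("max_mito_fraction must lie in [0, 1]")
  }
  structure(list(min_detected_genes = as.integer(min_detected_genes),
                 max_mito_fraction = max_mito_fraction), class = "qc_params")
}

#' Filter cells by detected-gene count and mitochondrial fraction
#'
#' Keeps cells with `detected_genes >= min_detected_genes` and
#' `mito_fraction <= max_mito_fraction`.
#'
#' @param expr Expression matrix, genes x cells.
#' @param cell_meta Data frame with columns `cell_id`, `detected_genes`,
#'   `mito_fraction` (rows matching the columns of `expr`).
#' @param params A [qc_params()].
#' @return List with `expr`, `cell_meta` (filtered) and `report` (counts
#'   removed per criterion).
#' @export
qc_filter <- function(expr, cell_meta, params = qc_params()) {
  stopifnot(all(c("cell_id", "detected_genes", "mito_fraction") %in% names(cell_meta)))
  m <- cell_meta[match(colnames(expr), cell_meta$cell_id), ]
  if (any(is.na(m$cell_id))) stop_ansd("cell_meta does not cover all expression columns")
  low_genes <- m$detected_genes < params$min_detected_genes
  high_mito <- m$mito_fraction > params$max_mito_fraction
  keep <- !(low_genes | high_mito)
  if (!any(keep)) stop_ansd("QC removed all cells")
  list(expr = expr[, keep, drop = FALSE],
       cell_meta = m[keep, , drop = FALSE],
       report = list(n_input = ncol(expr), n_kept = sum(keep),
                     removed_low_genes = sum(low_genes),
                     removed_high_mito = sum(high_mito)))
}

#' Library-size normalization followed by log2 transform
#'
#' Each unit (column) is scaled to a common library size (`scale_factor`
#' total) and transformed as `log2(x + 1)`.
#'
#' @param expr Non-negative expression matrix, genes x units.
#' @param scale_factor Target library size (10,000).
#' @return Normalized matrix of the same shape.
#' @export
normalize_log <- function(expr, scale_factor = 1e4) {
  if (any(expr < 0)) stop_ansd("expression values must be non-negative")
  totals <- colSums(expr)
  if (any(totals == 0)) {
    stop_ansd("unit(s) with zero total expression: ",
              paste(utils::head(colnames(expr)[totals == 0], 5), collapse = ", "))
  }
  log2(sweep(expr, 2, totals, "/") * scale_factor + 1)
}

#' Malignant-versus-rest differential expression screen (Gy)
#'
#' Per gene, a two-sided rank-sum test of malignant cells against all other
#' cells on log-scale expression. The fold change is computed on the
#' back-transformed scale:
#' `logFC = log2((mean(2^x_mal - 1) + 1) / (mean(2^x_rest - 1) + 1))`.
#' Benjamini-Hochberg adjustment across all tested genes. `Gy` keeps genes
#' with `logFC >= logfc_cut` and `q < q_cut` - the positive direction only,
#' because the candidate set is defined as genes with higher expression in
#' malignant cells.
#'
#' @param expr Log-scale expression matrix, genes x cells.
#' @param cell_types Character vector per cell; cells labelled
#'   `malignant_label` form the malignant group.
#' @param logfc_cut Log2 fold-change threshold (0.30).
#' @param q_cut FDR threshold (1e-5).
#' @param malignant_label Label identifying malignant cells.
#' @return List with `de` (data.frame: gene, logFC, p_value, q_value) and
#'   `Gy` (character vector).
#' @export
malignant_de_screen <- function(expr, cell_types, logfc_cut = 0.30,
                                q_cut = 1e-5, malignant_label = "malignant") {
  stopifnot(length(cell_types) == ncol(expr))
  mal <- cell_types == malignant_label
  if (!any(mal)) stop_ansd("no cells labelled '", malignant_label, "'")
  if (sum(mal) < 2L || sum(!mal) < 2L) stop_ansd("need >= 2 cells per group")
  lin <- 2^expr - 1  # back-transform for the fold-change means
  mean_mal <- rowMeans(lin[, mal, drop = FALSE])
  mean_rest <- rowMeans(lin[, !mal, drop = FALSE])
  logfc <- log2((mean_mal + 1) / (mean_rest + 1))
  pvals <- vapply(seq_len(nrow(expr)), function(i) {
    rank_sum_test(expr[i, mal], expr[i, !mal])$p_value
  }, 0)
  qvals <- bh_adjust(pvals)
  de <- data.frame(gene = rownames(expr), logFC = logfc, p_value = pvals,
                   q_value = qvals, stringsAsFactors = FALSE, row.names = NULL)
  Gy <- de$gene[de$logFC >= logfc_cut & de$q_value < q_cut]
  list(de = de, Gy = sort(Gy))
}

#' Program-score correlation screen in malignant cells (Gx)
#'
#' Per gene, the Spearman correlation against the per-cell program score
#' (e.g. the ssGSEA ANSD score). `Gx` keeps genes with `rho > rho_cut` and
#' raw `p < p_cut`; set `adjust = TRUE` to apply BH and filter on q instead.
#'
#' @param expr_malignant Expression matrix restricted to malignant cells.
#' @param scores Numeric per-cell score, aligned with the columns (names
#'   matched when present).
#' @param rho_cut,p_cut Positive-correlation and significance thresholds
#'   (0.3 and 0.05).
#' @param adjust Apply BH across genes before filtering.
#' @return List with `corr` (gene, rho, p_value[, q_value]) and `Gx`.
#' @export
ansd_correlation_screen <- function(expr_malignant, scores, rho_cut = 0.3,
                                    p_cut = 0.05, adjust = FALSE) {
  if (!is.null(names(scores))) {
    scores <- scores[colnames(expr_malignant)]
    if (any(is.na(scores))) stop_ansd("scores missing for some malignant cells")
  }
  stopifnot(length(scores) == ncol(expr_malignant))
  if (ncol(expr_malignant) < 3L) stop_ansd("need >= 3 malignant cells")
  res <- lapply(seq_len(nrow(expr_malignant)), function(i) {
    x <- expr_malignant[i, ]
    if (stats::sd(x) == 0) return(c(NA_real_, NA_real_))
    tt <- spearman_corr(x, scores)
    c(tt$effect, tt$p_value)
  })
  res <- do.call(rbind, res)
  corr <- data.frame(gene = rownames(expr_malignant), rho = res[, 1],
                     p_value = res[, 2], stringsAsFactors = FALSE,
                     row.names = NULL)
  crit <- if (adjust) {
    corr$q_value <- bh_adjust(corr$p_value)
    !is.na(corr$rho) & corr$rho > rho_cut & corr$q_value < p_cut
  } else {
    !is.na(corr$rho) & corr$rho > rho_cut & corr$p_value < p_cut
  }
  list(corr = corr, Gx = sort(corr$gene[crit]))
}

#' Per-dataset candidate sets Gx, Gy and their intersection Gn
#'
#' @param dataset_id Dataset identifier.
#' @param Gx Score-correlated genes.
#' @param Gy Malignant-upregulated genes.
#' @return A list of class `candidate_sets` with `Gn = intersect(Gx, Gy)`.
#' @export
candidate_sets <- function(dataset_id, Gx, Gy) {
  structure(list(dataset_id = dataset_id, Gx = sort(unique(Gx)),
                 Gy = sort(unique(Gy)),
                 Gn = sort(intersect(Gx, Gy))),
            class = "candidate_sets")
}

#' Merge per-dataset Gn sets into a signature
#'
#' The signature is the sorted, deduplicated union of all per-dataset Gn
#' sets; provenance records which datasets contributed each gene.
#'
#' @param sets List of [candidate_sets()].
#' @param name Signature name.
#' @return A list of class `ansd_signature` with `genes` and `provenance`.
#' @export
derive_signature <- function(sets, name = "signature") {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "candidate_sets")))
  genes <- sort(unique(unlist(lapply(sets, `[[`, "Gn"))))
  if (length(genes) == 0L) {
    warning("empty signature: no gene survived any dataset's Gn", call. = FALSE)
  }
  provenance <- lapply(stats::setNames(genes, genes), function(g) {
    unlist(lapply(sets, function(s) if (g %in% s$Gn) s$dataset_id))
  })
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "ansd_signature")
}

#' @export
print.ansd_signature <- function(x, ...) {
  cat(sprintf("Signature '%s': %d gene(s)\n", x$name, length(x$genes)))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end signature derivation over several single-cell datasets
#'
#' Runs, per dataset: QC filter, optional normalization, ssGSEA scoring of
#' the program gene set on malignant cells, the differential-expression
#' screen (Gy) and the correlation screen (Gx), then merges the per-dataset
#' intersections into a signature.
#'
#' @param datasets List of lists with elements `expr`, `cell_meta` (and
#'   optionally `id`).
#' @param program_set Character vector: the scoring gene set (e.g. the ANSD
#'   set).
#' @param qc A [qc_params()].
#' @param normalize Library-size/log normalize the matrices first (disable
#'   when the input is already on a normalized log scale).
#' @param rho_cut,p_cut,logfc_cut,q_cut Screen thresholds.
#' @return List with `signature` ([derive_signature()] output) and
#'   `candidates` (per-dataset [candidate_sets()]).
#' @export
run_signature_pipeline <- function(datasets, program_set, qc = qc_params(),
                                   normalize = TRUE, rho_cut = 0.3,
                                   p_cut = 0.05, logfc_cut = 0.30,
                                   q_cut = 1e-5) {
  cands <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    id <- d$id %||% sprintf("dataset%d", i)
    f <- qc_filter(d$expr, d$cell_meta, qc)
    expr <- if (normalize) normalize_log(f$expr) else f$expr
    mal <- f$cell_meta$cell_type == "malignant"
    scores <- ssgsea_scores(expr[, mal, drop = FALSE], list(program = program_set),
                            normalize = FALSE)["program", ]
    gx <- ansd_correlation_screen(expr[, mal, drop = FALSE], scores,
                                  rho_cut = rho_cut, p_cut = p_cut)
    gy <- malignant_de_screen(expr, f$cell_meta$cell_type,
                              logfc_cut = logfc_cut, q_cut = q_cut)
    candidate_sets(id, gx$Gx, gy$Gy)
  })
  list(signature = derive_signature(cands), candidates = cands)
}
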