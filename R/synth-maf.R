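# Mutation-table and infiltration-abundance generators for the subtyping
# stage.

#' Configuration for a synthetic MAF-like mutation table
#'
#' @param cluster_sizes Named integer vector: samples per cluster.
#' @param mutation_probs Numeric matrix, genes x clusters (dimnames
#'   required): per-cluster Bernoulli mutation probability per gene.
#' @param seed Integer seed.
#' @return A list of class `maf_config`.
#' @export
maf_config <- function(cluster_sizes = c(A = 100L, B = 100L),
                       mutation_probs = default_mutation_probs(),
                       seed = 1L) {
  if (any(mutation_probs < 0 | mutation_probs > 1)) {
    stop_ansd("mutation probabilities must lie in [0, 1]")
  }
  if (is.null(rownames(mutation_probs)) || is.null(colnames(mutation_probs))) {
    stop_ansd("mutation_probs needs gene rownames and cluster colnames")
  }
  if (!all(colnames(mutation_probs) %in% names(cluster_sizes))) {
    stop_ansd("mutation_probs columns must match cluster names")
  }
  structure(list(cluster_sizes = cluster_sizes,
                 mutation_probs = mutation_probs, seed = seed),
            class = "maf_config")
}

#' Default per-cluster mutation probabilities
#'
#' A small panel of recurrently mutated gastric-cancer genes with
#' cluster-skewed frequencies.
#' @return Numeric matrix genes x clusters.
#' @export
default_mutation_probs <- function() {
  m <- rbind(TTN = c(0.58, 0.35), TP53 = c(0.51, 0.30), MUC16 = c(0.30, 0.25),
             LRP1B = c(0.25, 0.10), ARID1A = c(0.20, 0.28), CDH1 = c(0.05, 0.18))
  colnames(m) <- c("A", "B")
  m
}

#' Generate a synthetic MAF-like mutation table
#'
#' One Bernoulli draw per (sample, gene); mutated pairs emit one row with a
#' variant class sampled from common non-silent classes. Occasional duplicate
#' rows for the same pair are NOT generated; duplicate handling is exercised
#' separately in tests.
#'
#' @param config A [maf_config()].
#' @return List with `maf` (Hugo_Symbol, Tumor_Sample_Barcode,
#'   Variant_Classification) and `truth` (named cluster vector).
#' @export
make_maf <- function(config) {
  stopifnot(inherits(config, "maf_config"))
  with_seed(config$seed, {
    clusters <- rep(names(config$cluster_sizes), config$cluster_sizes)
    samples <- sprintf("TCGA-%04d", seq_along(clusters))
    genes <- rownames(config$mutation_probs)
    classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                 "Splice_Site", "Silent")
    rows <- list()
    for (g in genes) {
      p <- config$mutation_probs[g, clusters]
      hit <- stats::runif(length(samples)) < p
      if (any(hit)) {
        rows[[g]] <- data.frame(
          Hugo_Symbol = g,
          Tumor_Sample_Barcode = samples[hit],
          Variant_Classification = sample(classes, sum(hit), replace = TRUE,
                                          prob = c(0.55, 0.15, 0.1, 0.1, 0.1)),
          stringsAsFactors = FALSE)
      }
    }
    maf <- if (length(rows)) do.call(rbind, rows) else
      data.frame(Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
                 Variant_Classification = character(), stringsAsFactors = FALSE)
    rownames(maf) <- NULL
    list(maf = maf, truth = list(clusters = stats::setNames(clusters, samples),
                                 config = config))
  })
}

#' Generate a synthetic immune-infiltration abundance table
#'
#' Selected cell-type abundance rows are generated to correlate with named
#' genes of `expr` at the target Spearman rho; remaining rows are
#' independent noise.
#'
#' @param expr Expression matrix (genes x samples).
#' @param coupled_genes Genes each driving one coupled cell-type row.
#' @param rho Target Spearman correlation (0 for uncoupled noise rows only).
#' @param n_celltypes Total number of cell-type rows (>= number coupled).
#' @param seed Integer seed.
#' @return List with `abundance` (cell types x samples) and `truth`.
#' @export
make_infiltration <- function(expr, coupled_genes = character(), rho = 0.35,
                              n_celltypes = 28L, seed = 1L) {
  bad <- setdiff(coupled_genes, rownames(expr))
  if (length(bad)) stop_ansd("coupled genes absent from expr: ", paste(bad, collapse = ", "))
  if (n_celltypes < length(coupled_genes)) stop_ansd("n_celltypes too small")
  n <- ncol(expr)
  with_seed(seed, {
    ab <- matrix(stats::rnorm(n_celltypes * n), n_celltypes, n)
    ct <- sprintf("celltype_%02d", seq_len(n_celltypes))
    rownames(ab) <- ct
    colnames(ab) <- colnames(expr)
    coupled_types <- character()
    if (length(coupled_genes) && rho != 0) {
      r_p <- 2 * sin(pi * abs(rho) / 6) * sign(rho)
      for (i in seq_along(coupled_genes)) {
        g <- drop(scale(expr[coupled_genes[i], ]))
        ab[i, ] <- r_p * g + sqrt(1 - r_p^2) * stats::rnorm(n)
      }
      coupled_types <- ct[seq_along(coupled_genes)]
    }
    list(abundance = ab,
         truth = list(coupled = stats::setNames(coupled_genes,
                                                coupled_types),
                      rho = rho))
  })
}
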