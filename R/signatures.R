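# Published signature gene lists shipped with the package. Symbols are the
# HGNC identifiers of the derived ANSD-related signature and its consensus
# hub subset; both are development-associated transcription-factor-heavy sets.

#' The 20-gene ANSD-related differential signature (ANSDR.Sig)
#'
#' Genes upregulated in malignant cells and positively correlated with the
#' autonomic-nervous-system-development enrichment score across single-cell
#' tumor datasets.
#'
#' @return Character vector of 20 unique gene symbols, as published.
#' @export
ansdr_sig <- function() {
  c("CTNNB1", "GATA3", "NRP2", "SOX4", "TFAP2A", "TP63", "HES1", "SOX11",
    "ASCL1", "FZD3", "NAV2", "SOX8", "FN1", "INSM1", "TFAP2B", "NF1",
    "NRP1", "SIX1", "EDNRB", "SOX10")
}

#' The 18-gene consensus hub subset (Hub-ANSDR.Sig)
#'
#' Members of [ansdr_sig()] selected by at least three of five feature
#' selectors against immunotherapy response.
#'
#' @return Character vector of 18 unique gene symbols, as published.
#' @export
hub_ansdr_sig <- function() {
  c("ASCL1", "CTNNB1", "EDNRB", "FN1", "FZD3", "GATA3", "HES1", "INSM1",
    "NAV2", "NF1", "NRP1", "NRP2", "SIX1", "SOX11", "SOX4", "SOX8",
    "TFAP2A", "TP63")
}
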