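# Plain-text interchange: GMT gene sets, TSV matrices/tables, MatrixMarket
# triples. All readers return base-R objects (character vectors, matrices,
# data.frames) so the pipeline has no container dependencies.

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (name, description, members...).
#' @return Named list of unique gene-symbol character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-symbol vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "ansdsig", unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV: first column = gene symbols, remaining columns = units. MatrixMarket:
#' `path` is the `.mtx` file, with sibling `rows.txt` / `cols.txt` name files
#' (one name per line) unless given explicitly.
#'
#' @param path Path to a `.tsv`/`.txt` table or a `.mtx` file.
#' @param rows,cols Optional name-file paths for the MatrixMarket layout.
#' @return Dense numeric matrix, genes x units.
#' @export
read_expression <- function(path, rows = NULL, cols = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop_ansd("reading .mtx requires the Matrix package")
    }
    m <- as.matrix(Matrix::readMM(path))
    rows <- rows %||% file.path(dirname(path), "rows.txt")
    cols <- cols %||% file.path(dirname(path), "cols.txt")
    rownames(m) <- readLines(rows, warn = FALSE)
    colnames(m) <- readLines(cols, warn = FALSE)
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix, genes x units.
#' @param path Output path.
#' @param id_column Name of the leading identifier column.
#' @export
write_expression <- function(expr, path, id_column = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
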