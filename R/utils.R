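#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_ansd <- function(...) stop(..., call. = FALSE)

check_binary <- function(x, name = "labels") {
  x <- as.integer(x)
  if (any(is.na(x)) || !all(x %in% c(0L, 1L))) {
    stop_ansd(sprintf("'%s' must be binary (0/1)", name))
  }
  x
}

# Average ranks (midranks), the tie convention used throughout the package.
avg_rank <- function(x) rank(x, ties.method = "average")

`%||%` <- function(a, b) if (is.null(a)) b else a
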