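# Pooled immune-checkpoint-inhibitor cohort generator: batched expression
# with a planted responder effect, RECIST labels, and censored survival tied
# to the effect-gene program.

#' Configuration for a synthetic pooled ICI cohort
#'
#' Defaults mirror the pooled study design this package targets: three
#' batches of 181, 348 and 243 samples (n = 772 in total).
#'
#' @param batch_sizes Integer vector of samples per batch.
#' @param n_genes Gene-universe size.
#' @param batch_shift Per-batch gene-mean offsets: either a single SD (each
#'   batch gets gene-wise `N(0, batch_shift)` offsets) or a numeric vector of
#'   one constant offset per batch.
#' @param response_rate Responder (CR/PR) fraction in (0, 1); 0.3 by default,
#'   a typical ICI objective-response rate.
#' @param effect_genes Genes shifted in responders (default: the first 20
#'   universe genes).
#' @param effect_d Standardized shift d applied to `effect_genes` in
#'   responders.
#' @param baseline_hazard Exponential baseline hazard for overall survival.
#' @param hazard_ratio Hazard ratio per unit of the (standardized)
#'   effect-gene program score.
#' @param censoring_rate Independent exponential censoring rate as a fraction
#'   of the baseline hazard, in `[0, 1)`.
#' @param noise_sd Expression noise SD.
#' @param seed Integer seed.
#' @return A list of class `ici_config`.
#' @export
ici_config <- function(batch_sizes = c(181L, 348L, 243L), n_genes = 500L,
                       batch_shift = 1.0, response_rate = 0.3,
                       effect_genes = NULL, effect_d = 1.5,
                       baseline_hazard = 0.1, hazard_ratio = 2,
                       censoring_rate = 0.3, noise_sd = 1.0, seed = 1L) {
  if (response_rate <= 0 || response_rate >= 1) stop_ansd("response_rate must be in (0, 1)")
  if (censoring_rate < 0 || censoring_rate >= 1) stop_ansd("censoring_rate must be in [0, 1)")
  structure(as.list(environment()), class = "ici_config")
}

#' Generate a synthetic batched ICI cohort
#'
#' Responders (CR/PR, drawn at `response_rate`) have `effect_genes` shifted
#' by `effect_d` standardized units. Survival times are exponential with
#' hazard proportional to `exp(log(hazard_ratio) * program)` where `program`
#' is the standardized mean expression of the effect genes; censoring is
#' independent.
#'
#' @param config An [ici_config()].
#' @return List with `expr` (genes x samples), `clinical` (sample_id, batch,
#'   recist, response, os_time, os_event) and `truth`.
#' @export
make_ici_cohort <- function(config) {
  stopifnot(inherits(config, "ici_config"))
  genes <- gene_universe(config$n_genes)
  effect_genes <- config$effect_genes %||% genes[seq_len(min(20L, config$n_genes))]
  bad <- setdiff(effect_genes, genes)
  if (length(bad)) stop_ansd("effect genes outside universe: ", paste(bad, collapse = ", "))
  with_seed(config$seed, {
    n_batches <- length(config$batch_sizes)
    n <- sum(config$batch_sizes)
    batch <- rep(sprintf("batch%d", seq_len(n_batches)), config$batch_sizes)
    sample_id <- sprintf("S%04d", seq_len(n))
    base <- stats::runif(config$n_genes, 2, 8)
    if (length(config$batch_shift) == 1L) {
      shifts <- matrix(stats::rnorm(config$n_genes * n_batches,
                                    sd = config$batch_shift),
                       config$n_genes, n_batches)
    } else {
      stopifnot(length(config$batch_shift) == n_batches)
      shifts <- matrix(rep(config$batch_shift, each = config$n_genes),
                       config$n_genes, n_batches)
    }
    responder <- stats::rbinom(n, 1, config$response_rate)
    expr <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                   config$n_genes, n, dimnames = list(genes, sample_id)) +
      base + shifts[, as.integer(factor(batch, levels = unique(batch)))]
    expr[effect_genes, responder == 1L] <-
      expr[effect_genes, responder == 1L] + config$effect_d * config$noise_sd
    expr[expr < 0] <- 0
    # RECIST: responders split CR/PR, non-responders SD/PD, 50/50 each; only
    # the binary encoding matters downstream
    recist <- ifelse(responder == 1L,
                     sample(c("CR", "PR"), n, replace = TRUE),
                     sample(c("SD", "PD"), n, replace = TRUE))
    program <- drop(scale(colMeans(expr[effect_genes, , drop = FALSE])))
    haz <- config$baseline_hazard * config$hazard_ratio^program
    t_event <- stats::rexp(n, rate = haz)
    os_time <- t_event
    os_event <- rep(1L, n)
    if (config$censoring_rate > 0) {
      t_cens <- stats::rexp(n, rate = config$baseline_hazard *
                              config$censoring_rate / (1 - config$censoring_rate))
      os_event <- as.integer(t_event <= t_cens)
      os_time <- pmin(t_event, t_cens)
    }
    clinical <- data.frame(sample_id = sample_id, batch = batch,
                           recist = recist, response = responder,
                           os_time = os_time, os_event = os_event,
                           stringsAsFactors = FALSE)
    truth <- list(effect_genes = effect_genes, responder = responder,
                  program = stats::setNames(program, sample_id),
                  batch_shifts = shifts, config = config)
    list(expr = expr, clinical = clinical, truth = truth)
  })
}
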