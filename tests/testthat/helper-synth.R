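# Shared fixture builders: everything is generated in code at test time.

genes_n <- function(n) sprintf("G%04d", seq_len(n))

# two well-separated Gaussian blobs; returns features x samples plus truth
make_blobs <- function(n_per = 50L, n_features = 10L, separation = 10,
                       seed = 1L) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_features * n_per), n_features, n_per)
    b <- matrix(rnorm(n_features * n_per) + separation, n_features, n_per)
    x <- cbind(a, b)
    colnames(x) <- sprintf("S%03d", seq_len(2L * n_per))
    rownames(x) <- sprintf("F%02d", seq_len(n_features))
    list(expr = x, truth = rep(1:2, each = n_per))
  })
}

# exponential survival with hazard 2^score (HR = 2 per unit), light censoring
sim_survival <- function(score, baseline = 0.1, censor_rate = 0.03,
                         seed = 1L) {
  withr::with_seed(seed, {
    t_event <- rexp(length(score), rate = baseline * 2^score)
    t_cens <- rexp(length(score), rate = censor_rate)
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  })
}

# naive running-sum ssGSEA oracle: direct loop over the published formula
naive_ssgsea_es <- function(x, gene_names, set, alpha) {
  N <- length(x)
  ord <- order(-x, order(order(gene_names)))
  es <- 0
  p_in <- 0
  p_out <- 0
  w_total <- 0
  for (i in seq_len(N)) if (gene_names[ord[i]] %in% set) {
    w_total <- w_total + (N - i + 1)^alpha
  }
  n_out <- N - sum(gene_names %in% set)
  for (i in seq_len(N)) {
    g <- gene_names[ord[i]]
    if (g %in% set) p_in <- p_in + (N - i + 1)^alpha / w_total
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
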