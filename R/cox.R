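# Cox proportional-hazards fit by Newton-Raphson on the Breslow partial
# likelihood. Kept deliberately small: no stratification, no penalties; the
# risk-model stage only needs point estimates of the coefficients.

breslow_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  o <- order(time)
  time <- time[o]; event <- event[o]; eta <- eta[o]
  # risk set at t_i = all with time >= t_i; walk from largest time down
  n <- length(time)
  ll <- 0
  exp_eta <- exp(eta)
  # cumulative sum of exp(eta) over the risk set, computed from the end
  rev_cum <- rev(cumsum(rev(exp_eta)))
  # Breslow: each event contributes eta_i - log(sum over risk set), where the
  # risk-set sum is taken at the event time (ties share the same risk set)
  for (t in unique(time[event == 1L])) {
    idx <- which(time == t & event == 1L)
    first <- which(time >= t)[1L]
    ll <- ll + sum(eta[idx]) - length(idx) * log(rev_cum[first])
  }
  ll
}

cox_score_info <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in unique(time[event == 1L])) {
    risk <- time >= t
    idx <- which(time == t & event == 1L)
    d <- length(idx)
    wr <- w[risk]
    S0 <- sum(wr)
    Xr <- X[risk, , drop = FALSE]
    S1 <- colSums(Xr * wr)
    xbar <- S1 / S0
    U <- U + colSums(X[idx, , drop = FALSE]) - d * xbar
    S2 <- crossprod(Xr, Xr * wr)
    I <- I + d * (S2 / S0 - tcrossprod(xbar))
  }
  list(U = U, I = I)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving, starting at beta = 0. Convergence when the maximum absolute score
#' component falls below `tol` (default 1e-8), or after `max_iter` iterations.
#' Monotone likelihood (complete separation) is reported via
#' `converged = FALSE` and a diagnostic message rather than an error.
#'
#' @param X Numeric matrix, samples x covariates.
#' @param time Positive follow-up times.
#' @param event Binary event indicator.
#' @param tol,max_iter Convergence tolerance on the score and iteration cap.
#' @return A list of class `cox_fit` with elements `coefficients`,
#'   `converged`, `log_partial_likelihood`, `iterations`, `diagnostic`.
#' @export
fit_cox <- function(X, time, event, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  event <- check_binary(event, "event")
  keep <- is.finite(time) & rowSums(!is.finite(X)) == 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("fit_cox: dropped %d rows with missing survival or covariates", dropped))
    X <- X[keep, , drop = FALSE]; time <- time[keep]; event <- event[keep]
  }
  if (sum(event) < 2L) stop_ansd("need at least 2 events")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_ansd("zero-variance covariate(s): ",
              paste(colnames(X)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)  # centering improves conditioning, leaves beta unchanged
  p <- ncol(X)
  beta <- numeric(p)
  ll <- breslow_loglik(beta, Xc, time, event)
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    si <- cox_score_info(beta, Xc, time, event)
    if (max(abs(si$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(si$I, si$U), error = function(e) NULL)
    if (is.null(step)) { diagnostic <- "singular information matrix"; break }
    # step halving to guarantee ascent
    ok <- FALSE
    for (h in 0:10) {
      cand <- beta + step / 2^h
      ll_new <- breslow_loglik(cand, Xc, time, event)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) { diagnostic <- "no ascent step found"; break }
    beta <- cand; ll <- ll_new
    if (max(abs(beta)) > 20) {
      diagnostic <- "monotone likelihood suspected (coefficient diverging); possible complete separation"
      break
    }
  }
  if (!converged) {
    si <- cox_score_info(beta, Xc, time, event)
    if (max(abs(si$U)) < tol) converged <- TRUE
    if (!converged && is.null(diagnostic)) diagnostic <- "iteration limit reached"
  }
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, converged = converged,
                 log_partial_likelihood = ll, iterations = iter,
                 diagnostic = diagnostic),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (Breslow):", if (x$converged) "converged" else
    paste("NOT converged -", x$diagnostic %||% ""),
    sprintf("after %d iterations\n", x$iterations))
  print(x$coefficients)
  invisible(x)
}
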