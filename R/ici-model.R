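# ICI response prediction: pool cohorts, remove batch effects, split 80/20,
# train classifiers on a signature's genes with repeated stratified
# cross-validation, and evaluate held-out AUC.

#' Encode RECIST labels as binary response
#'
#' CR and PR are responders (1); SD and PD are non-responders (0).
#'
#' @param recist Character vector of RECIST labels.
#' @return Integer 0/1 vector.
#' @export
encode_response <- function(recist) {
  bad <- setdiff(unique(recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    stop_ansd("unknown RECIST label(s): ", paste(bad, collapse = ", "))
  }
  as.integer(recist %in% c("CR", "PR"))
}

#' Remove batch effects from a pooled expression matrix
#'
#' Default method (`"location_scale"`): within each batch every gene is
#' centered to the pooled gene mean and rescaled so that the pooled
#' per-gene SD is preserved exactly; after correction, per-gene between-batch
#' mean differences vanish (to machine precision) and a second application is
#' a no-op. Genes with zero variance inside a batch are adjusted by location
#' only (logged). `method = "eb"` delegates to empirical-Bayes shrinkage of
#' the batch parameters (ComBat) when the sva package is available.
#'
#' @param expr Expression matrix, genes x samples.
#' @param batch Batch id per sample.
#' @param method `"location_scale"` (default) or `"eb"`.
#' @return Corrected matrix of the same shape.
#' @export
correct_batches <- function(expr, batch, method = c("location_scale", "eb")) {
  method <- match.arg(method)
  stopifnot(length(batch) == ncol(expr))
  batch <- as.character(batch)
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop_ansd("batch(es) with a single sample: ",
              paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (length(sizes) == 1L) return(expr)
  if (method == "eb") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      stop_ansd("method 'eb' requires the sva package")
    }
    return(sva::ComBat(dat = expr, batch = batch))
  }
  N <- ncol(expr); B <- length(sizes)
  m_g <- rowMeans(expr)
  s_g <- apply(expr, 1, stats::sd)
  fct <- sqrt((N - 1) / (N - B))
  out <- expr
  n_loc_only <- 0L
  for (b in names(sizes)) {
    idx <- batch == b
    xb <- expr[, idx, drop = FALSE]
    mb <- rowMeans(xb)
    sb <- apply(xb, 1, stats::sd)
    flat <- sb == 0 | s_g == 0
    n_loc_only <- n_loc_only + sum(flat)
    scale_to <- ifelse(flat, 1, (s_g * fct) / ifelse(sb == 0, 1, sb))
    out[, idx] <- (xb - mb) * scale_to + m_g
  }
  if (n_loc_only > 0) {
    message(sprintf("correct_batches: %d gene-batch pair(s) adjusted by location only (zero variance)",
                    n_loc_only))
  }
  out
}

#' Stratified train/validation split
#'
#' The training set holds `round(fraction * n)` samples; with
#' `stratify = TRUE`, per-class counts are apportioned by largest remainder
#' so class proportions differ by at most one sample.
#'
#' @param labels Binary 0/1 labels.
#' @param fraction Training fraction in (0, 1); 0.8 by default.
#' @param seed Integer seed (split is deterministic given the seed).
#' @param stratify Preserve class proportions.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(labels, fraction = 0.8, seed = 1L,
                                   stratify = TRUE) {
  labels <- check_binary(labels)
  if (fraction <= 0 || fraction >= 1) stop_ansd("fraction must be in (0, 1)")
  n <- length(labels)
  n_train <- round(fraction * n)
  train <- with_seed(seed, {
    if (!stratify) {
      sample(n, n_train)
    } else {
      cls <- sort(unique(labels))
      targ <- fraction * as.numeric(table(factor(labels, levels = cls)))
      base <- floor(targ)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(targ - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      unlist(lapply(seq_along(cls), function(i) {
        idx <- which(labels == cls[i])
        sample(idx, base[i])
      }))
    }
  })
  train <- sort(train)
  validation <- setdiff(seq_len(n), train)
  if (length(unique(labels[train])) < 2L || length(unique(labels[validation])) < 2L) {
    stop_ansd("split produced a single-class partition; adjust fraction or stratify")
  }
  list(train = train, validation = validation)
}

# ---- per-algorithm fit / score -------------------------------------------

ansd_algorithms <- function() {
  c("rf", "nb", "svm", "adaboost", "logitboost", "knn", "cancerclass")
}

default_grid <- function(algorithm, p) {
  switch(algorithm,
         rf = data.frame(mtry = unique(c(max(1L, floor(sqrt(p))),
                                         max(1L, floor(p / 3))))),
         nb = data.frame(laplace = c(0, 1)),
         svm = data.frame(cost = c(1, 10)),
         adaboost = data.frame(rounds = c(50L, 100L)),
         logitboost = data.frame(rounds = c(50L, 100L)),
         knn = data.frame(k = c(5L, 11L, 21L)),
         cancerclass = data.frame(.none = 0))
}

fit_adaboost_stumps <- function(x, y, rounds) {
  yy <- ifelse(y == 1L, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  ctl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                              minbucket = 1, xval = 0)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    dat <- cbind(df, .y = factor(yy, levels = c(-1, 1)))
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctl)
    pred <- as.numeric(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != yy))
    if (err >= 0.5) {
      if (length(stumps) == 0L) { stumps[[1]] <- fit; alphas[1] <- 0.01 }
      break
    }
    alpha <- if (err <= 0) 10 else 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas[length(alphas) + 1L] <- alpha
    if (err <= 0) break
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas), class = "ada_stumps")
}

score_adaboost_stumps <- function(fit, x) {
  df <- as.data.frame(x)
  F <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(stats::predict(fit$stumps[[m]], df,
                                                   type = "class")))
    F <- F + fit$alphas[m] * pred
  }
  1 / (1 + exp(-2 * F))
}

fit_logitboost_stumps <- function(x, y, rounds) {
  n <- nrow(x)
  df <- as.data.frame(x)
  ctl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                              minbucket = 1, xval = 0)
  F <- rep(0, n)
  stumps <- vector("list", rounds)
  for (m in seq_len(rounds)) {
    p <- 1 / (1 + exp(-2 * F))
    w <- pmax(p * (1 - p), 1e-5)
    z <- pmin(pmax((y - p) / w, -4), 4)
    dat <- cbind(df, .z = z)
    fit <- rpart::rpart(.z ~ ., data = dat, weights = w, method = "anova",
                        control = ctl)
    stumps[[m]] <- fit
    F <- F + 0.5 * stats::predict(fit, df)
  }
  structure(list(stumps = stumps), class = "logit_stumps")
}

score_logitboost_stumps <- function(fit, x) {
  df <- as.data.frame(x)
  F <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    F <- F + 0.5 * stats::predict(fit$stumps[[m]], df)
  }
  1 / (1 + exp(-2 * F))
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

fit_one_algorithm <- function(algorithm, x, y, params, ntree = 500L) {
  yf <- factor(y, levels = c(0, 1))
  switch(algorithm,
    rf = randomForest::randomForest(x, yf, ntree = ntree, mtry = params$mtry),
    nb = e1071::naiveBayes(as.data.frame(x), yf, laplace = params$laplace),
    svm = e1071::svm(x, yf, cost = params$cost, probability = TRUE,
                     kernel = "radial"),
    adaboost = fit_adaboost_stumps(x, y, params$rounds),
    logitboost = fit_logitboost_stumps(x, y, params$rounds),
    knn = {
      std <- standardize_fit(x)
      list(x = standardize_apply(x, std), y = y, k = params$k, std = std)
    },
    cancerclass = {
      # nearest centroid on standardized features; the prediction score is
      # the (continuous) distance difference to the two class centroids
      std <- standardize_fit(x)
      xs <- standardize_apply(x, std)
      list(centroid0 = colMeans(xs[y == 0L, , drop = FALSE]),
           centroid1 = colMeans(xs[y == 1L, , drop = FALSE]),
           std = std)
    },
    stop_ansd("unknown algorithm: ", algorithm))
}

score_one_algorithm <- function(algorithm, fit, x) {
  switch(algorithm,
    rf = stats::predict(fit, x, type = "prob")[, "1"],
    nb = stats::predict(fit, as.data.frame(x), type = "raw")[, "1"],
    svm = attr(stats::predict(fit, x, probability = TRUE),
               "probabilities")[, "1"],
    adaboost = score_adaboost_stumps(fit, x),
    logitboost = score_logitboost_stumps(fit, x),
    knn = {
      xs <- standardize_apply(x, fit$std)
      d2 <- outer(rowSums(xs^2), rowSums(fit$x^2), "+") - 2 * tcrossprod(xs, fit$x)
      apply(d2, 1, function(d) mean(fit$y[order(d)[seq_len(fit$k)]]))
    },
    cancerclass = {
      xs <- standardize_apply(x, fit$std)
      d0 <- sqrt(rowSums(sweep(xs, 2, fit$centroid0)^2))
      d1 <- sqrt(rowSums(sweep(xs, 2, fit$centroid1)^2))
      d0 - d1
    },
    stop_ansd("unknown algorithm: ", algorithm))
}

make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < k) {
      stop_ansd("cannot stratify: class ", cls, " has fewer samples than folds")
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a response classifier with repeated cross-validated tuning
#'
#' For every point of the hyperparameter grid, AUC is averaged over
#' `cv_folds` stratified folds repeated `cv_repeats` times with different
#' fold seeds; the best point is refit on the full training data. The
#' cancerclass algorithm (standardized nearest-centroid with a continuous
#' distance-difference score) has no hyperparameters and is fit directly on
#' the whole training set.
#'
#' @param x Training matrix, samples x features (signature genes).
#' @param y Binary 0/1 response.
#' @param algorithm One of `rf`, `nb`, `svm`, `adaboost`, `logitboost`,
#'   `knn`, `cancerclass`.
#' @param grid Optional hyperparameter data frame (one row per point);
#'   defaults per algorithm are small and documented.
#' @param cv_folds,cv_repeats Cross-validation folds (5) and seed
#'   repetitions (10).
#' @param seed Integer base seed.
#' @param ntree Trees for the random forest.
#' @return Object of class `ansd_model`: `fit`, `algorithm`, `best_params`,
#'   `cv_report` (grid point x repeat x fold AUCs), `cv_mean_auc`, `genes`.
#' @export
train_model <- function(x, y, algorithm = "rf", grid = NULL, cv_folds = 5L,
                        cv_repeats = 10L, seed = 1L, ntree = 500L) {
  algorithm <- match.arg(algorithm, ansd_algorithms())
  x <- as.matrix(x)
  y <- check_binary(y, "y")
  if (nrow(x) < 20L) stop_ansd("need at least 20 training samples")
  if (length(unique(y)) < 2L) stop_ansd("both classes must be present")
  grid <- grid %||% default_grid(algorithm, ncol(x))
  cv_report <- NULL
  if (algorithm != "cancerclass") {
    rows <- list()
    for (r in seq_len(cv_repeats)) {
      fold <- with_seed(seed + r, make_stratified_folds(y, cv_folds))
      for (g in seq_len(nrow(grid))) {
        for (f in seq_len(cv_folds)) {
          tr <- fold != f
          fit <- with_seed(seed + 1000L * r + f,
                           fit_one_algorithm(algorithm, x[tr, , drop = FALSE],
                                             y[tr], grid[g, , drop = FALSE],
                                             ntree))
          sc <- score_one_algorithm(algorithm, fit, x[!tr, , drop = FALSE])
          rows[[length(rows) + 1L]] <- data.frame(
            grid_id = g, rep = r, fold = f,
            auc = auc_score(sc, y[!tr]))
        }
      }
    }
    cv_report <- do.call(rbind, rows)
    mean_auc <- tapply(cv_report$auc, cv_report$grid_id, mean)
    best <- as.integer(names(which.max(mean_auc)))
  } else {
    best <- 1L
    mean_auc <- NA_real_
  }
  fit <- with_seed(seed, fit_one_algorithm(algorithm, x, y,
                                           grid[best, , drop = FALSE], ntree))
  structure(list(algorithm = algorithm, fit = fit,
                 best_params = grid[best, , drop = FALSE],
                 cv_report = cv_report,
                 cv_mean_auc = if (algorithm == "cancerclass") NA_real_
                               else unname(mean_auc[as.character(best)]),
                 genes = colnames(x)),
            class = "ansd_model")
}

#' Predict continuous response scores
#'
#' @param object An `ansd_model`.
#' @param newdata Matrix, samples x features (must contain the model's
#'   genes).
#' @param ... Unused.
#' @return Numeric score per sample (higher = more responder-like).
#' @export
predict.ansd_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$genes, colnames(newdata))
  if (length(miss)) stop_ansd("newdata lacks model genes: ", paste(miss, collapse = ", "))
  unname(score_one_algorithm(object$algorithm, object$fit,
                             newdata[, object$genes, drop = FALSE]))
}

#' Evaluate a model on a labelled cohort
#'
#' @param model An `ansd_model`.
#' @param x Matrix, samples x features.
#' @param y Binary 0/1 labels.
#' @return List with `auc`, `band` (`"uninformative"` <= 0.5, `"low"` to
#'   0.7, `"moderate"` to 0.9, `"high"` above), `roc` (fpr/tpr step points)
#'   and `scores`.
#' @export
evaluate_model <- function(model, x, y) {
  y <- check_binary(y, "y")
  if (length(unique(y)) < 2L) stop_ansd("both classes must be present")
  sc <- predict(model, x)
  auc <- auc_score(sc, y)
  band <- if (auc <= 0.5) "uninformative" else if (auc <= 0.7) "low"
          else if (auc <= 0.9) "moderate" else "high"
  o <- order(sc, decreasing = TRUE)
  tpr <- cumsum(y[o] == 1L) / sum(y == 1L)
  fpr <- cumsum(y[o] == 0L) / sum(y == 0L)
  roc <- data.frame(threshold = c(Inf, sc[o]), fpr = c(0, fpr), tpr = c(0, tpr))
  # keep one point per distinct threshold (the last, i.e. full tie block)
  roc <- roc[!duplicated(roc$threshold, fromLast = TRUE), ]
  list(auc = auc, band = band, roc = roc, scores = sc)
}

#' Compare signatures across cohorts under one training protocol
#'
#' Every signature is evaluated with the identical pipeline per cohort:
#' restrict to signature genes present in the cohort (coverage logged),
#' stratified 80/20 split, train with the requested algorithm, held-out AUC.
#'
#' @param signatures Named list of gene-symbol vectors.
#' @param cohorts Named list; each element a list with `expr` (genes x
#'   samples) and `labels` (binary response).
#' @param algorithm Classifier passed to [train_model()].
#' @param seed Base seed (same seed => same split per cohort for every
#'   signature).
#' @param ... Further arguments to [train_model()] (e.g. `cv_repeats`).
#' @return Numeric matrix of held-out AUCs, signatures x cohorts (NA for
#'   zero-coverage pairs).
#' @export
compare_signatures <- function(signatures, cohorts, algorithm = "rf",
                               seed = 1L, ...) {
  stopifnot(length(signatures) >= 1L, length(cohorts) >= 1L)
  if (is.null(names(signatures))) names(signatures) <- paste0("sig", seq_along(signatures))
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  out <- matrix(NA_real_, length(signatures), length(cohorts),
                dimnames = list(names(signatures), names(cohorts)))
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    y <- check_binary(co$labels, "labels")
    sp <- split_train_validation(y, seed = seed)
    for (sn in names(signatures)) {
      genes <- intersect(signatures[[sn]], rownames(co$expr))
      if (length(genes) == 0L) {
        warning(sprintf("signature '%s' has zero coverage in cohort '%s'", sn, cn),
                call. = FALSE)
        next
      }
      cov <- length(genes) / length(unique(signatures[[sn]]))
      if (cov < 1) {
        message(sprintf("compare_signatures: '%s' in '%s': coverage %.0f%%",
                        sn, cn, 100 * cov))
      }
      xm <- t(co$expr[genes, , drop = FALSE])
      mdl <- train_model(xm[sp$train, , drop = FALSE], y[sp$train],
                         algorithm = algorithm, seed = seed, ...)
      out[sn, cn] <- evaluate_model(mdl, xm[sp$validation, , drop = FALSE],
                                    y[sp$validation])$auc
    }
  }
  out
}
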