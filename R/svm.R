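#' Train a soft-margin kernel classifier
#'
#' Binary maximum-margin classification of tumour feature vectors. The
#' standard soft-margin dual
#' `min 1/2 a' (K * yy') a - 1'a` subject to `0 <= a <= C`, `y'a = 0`
#' is solved with the interior-point QP solver from \pkg{kernlab}
#' (`ipop`); the kernels themselves are the package's own
#' ([kernel_spec()]). Features are standardised to zero mean / unit variance
#' by default (constant columns are left unscaled); the bias is recovered
#' from the unbounded support vectors.
#'
#' @param x Numeric feature matrix, one sample per row.
#' @param y Labels: logical, a factor with two levels, or `+1`/`-1`; the
#'   positive class is `TRUE`, the second factor level, or `+1`.
#' @param spec A [kernel_spec()].
#' @param C Soft-margin cost (> 0).
#' @param standardize Standardise features before training.
#' @return An object of class `"kernel_svm"` with `alpha`, `bias`, support
#'   vectors and the scaling; use [predict()] for decision values or labels.
#' @export
#' @examples
#' x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
#' y <- c(TRUE, TRUE, FALSE, FALSE)  # XOR pattern
#' fit <- kernel_svm(x, y, kernel_spec("grbf", sigma = 1), C = 10)
#' predict(fit, x)  # perfectly separated by the Gaussian kernel
kernel_svm <- function(x, y, spec = kernel_spec("grbf"), C = 1,
                       standardize = TRUE) {
  x <- as_points(x)
  yin <- y
  if (is.factor(y)) y <- y == levels(y)[2]
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be logical, a two-level factor, or +/-1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training data", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  n <- nrow(x)

  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    xs <- x
  }

  K <- kernel_matrix(spec, xs)
  H <- (K + 1e-8 * diag(n)) * tcrossprod(y)
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0)
  alpha <- as.numeric(kernlab::primal(sol))
  alpha[alpha < 1e-8] <- 0
  sv <- which(alpha > 0)

  f_no_bias <- as.numeric(K[, sv, drop = FALSE] %*% (alpha[sv] * y[sv]))
  free <- which(alpha > 1e-6 & alpha < C - 1e-6)
  bias <- if (length(free) > 0) mean(y[free] - f_no_bias[free])
          else mean(y[sv] - f_no_bias[sv])

  structure(list(spec = spec, C = C, alpha = alpha[sv], y = y[sv],
                 sv = xs[sv, , drop = FALSE], bias = bias,
                 center = ctr, scale = scl, n = n,
                 levels = if (is.factor(yin)) levels(yin) else NULL,
                 call = match.call()),
            class = "kernel_svm")
}

#' @export
print.kernel_svm <- function(x, ...) {
  cat(sprintf("Kernel SVM (%s kernel, C = %g): %d support vectors of %d samples\n",
              x$spec$family, x$C, nrow(x$sv), x$n))
  invisible(x)
}

#' @export
#' @rdname kernel_svm
#' @param object A fitted `"kernel_svm"`.
#' @param newdata Feature matrix to predict.
#' @param type `"label"` (default) or `"decision"` for raw decision values.
#' @param ... Unused.
predict.kernel_svm <- function(object, newdata,
                               type = c("label", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as_points(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  K <- kernel_matrix(object$spec, xs, object$sv)
  f <- as.numeric(K %*% (object$alpha * object$y)) + object$bias
  if (type == "decision") return(f)
  lab <- ifelse(f >= 0, 1, -1)
  if (!is.null(object$levels)) factor(object$levels[(lab + 3) / 2],
                                      levels = object$levels) else lab
}

#' Sensitivity, specificity and accuracy of a classifier
#'
#' Scores predictions on a labelled test set:
#' sensitivity `= 100 TP / (TP + FN)`, specificity `= 100 TN / (TN + FP)`,
#' accuracy `= 100 (TP + TN) / n`. A missing class in the truth yields `NA`
#' for the affected rate.
#'
#' @param model A fitted `"kernel_svm"` (or `NULL` if `pred` is supplied).
#' @param x Feature matrix.
#' @param y True labels (same encoding as in [kernel_svm()]).
#' @param pred Optional precomputed predictions (skips `model`).
#' @return Named vector `c(sensitivity, specificity, accuracy)` in percent.
#' @export
evaluate_classifier <- function(model, x, y, pred = NULL) {
  if (is.null(pred)) pred <- predict(model, x)
  to_pm <- function(v) {
    if (is.factor(v)) v <- v == levels(v)[2]
    if (is.logical(v)) v <- ifelse(v, 1, -1)
    as.numeric(v)
  }
  y <- to_pm(y); pred <- to_pm(pred)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == -1 & y == 1)
  tn <- sum(pred == -1 & y == -1); fp <- sum(pred == 1 & y == -1)
  c(sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(y))
}

#' k-fold cross-validated classifier performance
#'
#' Stratified k-fold cross-validation of [kernel_svm()]; reports the pooled
#' sensitivity, specificity and accuracy over held-out folds.
#'
#' @inheritParams kernel_svm
#' @param folds Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return Named vector as in [evaluate_classifier()], computed on the
#'   pooled out-of-fold predictions.
#' @export
svm_cv <- function(x, y, spec = kernel_spec("grbf"), C = 1, folds = 5L,
                   seed = 1L, standardize = TRUE) {
  x <- as_points(x)
  yl <- if (is.factor(y)) y == levels(y)[2] else if (is.logical(y)) y else y > 0
  n <- nrow(x)
  rng <- local_rng(seed)
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(yl == cls)
    fold[idx] <- (rng$sample_int(length(idx), length(idx)) %% folds) + 1L
  }
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    te <- which(fold == k)
    if (length(te) == 0L) next
    fit <- kernel_svm(x[-te, , drop = FALSE], yl[-te], spec = spec, C = C,
                      standardize = standardize)
    pred[te] <- predict(fit, x[te, , drop = FALSE])
  }
  evaluate_classifier(NULL, x, yl, pred = pred)
}
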