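#' Mean squared error between two images
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Mean of squared per-pixel differences.
#' @export
mse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have identical shapes", call. = FALSE)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; `Inf` for identical images.
#'
#' @inheritParams mse
#' @param peak Peak intensity (255 for 8-bit images).
#' @return PSNR in dB (`Inf` when the MSE is zero).
#' @export
psnr <- function(a, b, peak = 255) {
  e <- mse(a, b)
  if (e == 0) return(Inf)
  10 * log10(peak^2 / e)
}

#' Pixelwise confusion rates of a binary mask against ground truth
#'
#' Rates are percentages: `TPR = 100 TP / (TP + FN)`,
#' `TNR = 100 TN / (TN + FP)`, `FPR = 100 - TNR`, `FNR = 100 - TPR`, and the
#' accuracy convention is the balanced form `accuracy = (TPR + TNR) / 2`
#' (the arithmetic that links the TP/TN columns of a per-image score table to
#' its accuracy column). Note this accuracy is not symmetric in
#' `(pred, truth)`: the roles of positive truth and positive prediction
#' differ. If the truth lacks a class the affected rates are `NA`.
#'
#' @param pred Logical matrix (predicted mask).
#' @param truth Logical matrix (ground truth) of the same shape.
#' @return An object of class `"confusion_rates"`: a named list with `TPR`,
#'   `TNR`, `FPR`, `FNR`, `accuracy` (percentages) and the raw pixel counts.
#' @export
#' @examples
#' truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' pred <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
#' confusion_rates(pred, truth)  # TPR 50, TNR 100, accuracy 75
confusion_rates <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("masks must have identical shapes", call. = FALSE)
  stopifnot(is.logical(pred), is.logical(truth))
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tpr <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  tnr <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  acc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  structure(list(TPR = tpr, TNR = tnr, FPR = 100 - tnr, FNR = 100 - tpr,
                 accuracy = acc,
                 counts = c(TP = tp, TN = tn, FP = fp, FN = fn)),
            class = "confusion_rates")
}

#' @export
print.confusion_rates <- function(x, ...) {
  cat(sprintf("TPR %.3f  TNR %.3f  FPR %.3f  FNR %.3f  accuracy %.3f\n",
              x$TPR, x$TNR, x$FPR, x$FNR, x$accuracy))
  invisible(x)
}

#' @rdname confusion_rates
#' @param rates A `"confusion_rates"` object (or list of them).
#' @return `confusion_df` returns a one-row data frame per object with the
#'   percentage columns rounded to 3 decimals, mirroring a per-image score
#'   table.
#' @export
confusion_df <- function(rates) {
  if (inherits(rates, "confusion_rates")) rates <- list(rates)
  do.call(rbind, lapply(rates, function(r)
    data.frame(TP = round(r$TPR, 3), TN = round(r$TNR, 3),
               FP = round(r$FPR, 3), FN = round(r$FNR, 3),
               Accuracy = round(r$accuracy, 3))))
}

#' Dice overlap of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical shapes", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
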