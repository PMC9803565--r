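#' Segment a grayscale image by fuzzy intensity clustering
#'
#' Clusters per-pixel intensity (the 1-D feature the pipeline uses) with the
#' hybrid GCPSO-FCM optimiser (or plain FCM), assigns every pixel its
#' maximum-membership cluster, and relabels clusters in order of ascending
#' centre intensity, so label `c - 1` is always the brightest tissue class.
#' Intensities are binned to the 8-bit grid (`round(img)` by default) and
#' clustered once per distinct value via the image histogram
#' (membership-weighted with bin counts), which makes the cost independent of
#' image size; set `bin = FALSE` to cluster raw float intensities.
#'
#' @param img Numeric matrix in `[0, 255]` (ideally denoised).
#' @param c Number of clusters; must not exceed the number of distinct
#'   intensities.
#' @param method `"gcpso_fcm"` (default) or `"fcm"`.
#' @param m Fuzzifier.
#' @param seed Integer seed for the stochastic optimiser.
#' @param bin Round intensities to the integer grid before clustering.
#' @param ... Further arguments passed to [gcpso_fcm()] or [fcm()].
#' @return An object of class `"segmentation"`: `labels` (integer matrix with
#'   values `0 .. c-1`, ordered by centre intensity), `centers` (sorted
#'   centre intensities) and `fit` (the underlying `"fcm"` object).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(64, 64, tissue_means = c(0, 120, 230)))
#' seg <- segment_image(ph$image, c = 3)
#' mean(seg$labels == ph$labels)  # 1: noiseless phantom is exactly separable
segment_image <- function(img, c = 3L, method = c("gcpso_fcm", "fcm"),
                          m = 2, seed = 1L, bin = TRUE, ...) {
  img <- as_gray_matrix(img)
  method <- match.arg(method)
  c <- as.integer(c)
  if (bin) img <- round(img)
  vals <- sort(unique(as.numeric(img)))
  if (length(vals) < c)
    stop("image has only ", length(vals), " distinct intensities; ",
         "cannot form ", c, " clusters", call. = FALSE)
  counts <- as.numeric(table(factor(as.numeric(img), levels = vals)))

  fit <- if (method == "gcpso_fcm")
    gcpso_fcm(vals, centers = c, m = m, weights = counts, seed = seed, ...)
  else
    fcm(vals, centers = c, m = m, weights = counts, seed = seed, ...)

  ord <- order(fit$centers[, 1])
  # per-unique-value hard label (ties to the lowest re-ordered index)
  U_ord <- fit$U[, ord, drop = FALSE]
  val_lab <- apply(U_ord, 1, which.max) - 1L
  labels <- matrix(val_lab[match(as.numeric(img), vals)], nrow(img), ncol(img))

  if (length(unique(val_lab)) < c)
    warning("segmentation produced an empty cluster", call. = FALSE)

  structure(list(labels = labels, centers = fit$centers[ord, 1],
                 c = c, fit = fit),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d intensity clusters, centres %s\n", x$c,
              paste(round(x$centers, 2), collapse = ", ")))
  sizes <- tabulate(as.integer(x$labels) + 1L, nbins = x$c)
  cat("Pixel counts per label:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the tumour mask from a segmentation
#'
#' The tumour is the brightest tissue class, so the mask is the pixel set of
#' the highest label; optionally only its largest connected component is
#' kept, which removes isolated bright noise pixels.
#'
#' @param seg A `"segmentation"` object or an integer label matrix whose
#'   labels are ordered by ascending intensity.
#' @param keep_largest Keep only the largest 8-connected component
#'   (default `TRUE`).
#' @return Logical matrix, `TRUE` on tumour pixels (possibly empty).
#' @export
tumour_mask <- function(seg, keep_largest = TRUE) {
  labels <- if (inherits(seg, "segmentation")) seg$labels else seg
  stopifnot(is.matrix(labels))
  if (inherits(seg, "segmentation")) {
    top <- seg$c - 1L
  } else if (min(labels) == max(labels)) {
    # a flat label map has no bright cluster at all
    return(matrix(FALSE, nrow(labels), ncol(labels)))
  } else {
    top <- max(labels)
  }
  mask <- labels == top
  if (!any(mask) || !keep_largest) return(mask)
  comp <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(comp[comp > 0])
  mask & (comp == which.max(tab))
}
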