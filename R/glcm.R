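#' Quantise an 8-bit image to a number of gray levels
#'
#' Uniform binning of `[0, 255]`: bin index `floor(v * levels / 256)`,
#' clamped to `levels - 1`. With `levels = 256` this is the identity on
#' integer 8-bit input.
#'
#' @param img Numeric matrix with values in `[0, 255]`.
#' @param levels Number of gray levels (>= 2).
#' @return Integer matrix of bin indices `0 .. levels-1`.
#' @export
quantize <- function(img, levels = 256L) {
  img <- as_gray_matrix(img)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be at least 2", call. = FALSE)
  q <- floor(img * levels / 256)
  storage.mode(q) <- "integer"
  pmin(pmax(q, 0L), levels - 1L)
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered gray-level pairs `(p(r, c), p(r+dr, c+dc))` over all pixel
#' positions where both ends fall inside the image, normalised to sum to 1.
#' The offset convention is `(dr, dc)` with negative `dr` meaning upward, so
#' `(0,1)`, `(-1,1)`, `(-1,0)`, `(-1,-1)` are the 0, 45, 90 and 135 degree
#' directions. Matrices are directed (not symmetrised) unless requested.
#'
#' @param img Integer matrix from [quantize()] (values `0 .. levels-1`).
#' @param offset Integer pair `c(dr, dc)`, not both zero.
#' @param levels Number of gray levels in `img`.
#' @param symmetric If `TRUE`, also count each pair in the reverse direction.
#' @return A `levels` x `levels` matrix summing to 1; cell `[i+1, j+1]` holds
#'   the relative frequency of pair `(i, j)`.
#' @export
#' @examples
#' q <- matrix(c(0L, 1L, 1L, 0L), 2)
#' glcm(q, c(0, 1), levels = 2)  # mass 0.5 on (0,1) and on (1,0)
glcm <- function(img, offset, levels, symmetric = FALSE) {
  stopifnot(is.matrix(img))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop("offset must be a nonzero (dr, dc) pair", call. = FALSE)
  dr <- offset[1]; dc <- offset[2]
  h <- nrow(img); w <- ncol(img)
  if (abs(dr) >= h || abs(dc) >= w)
    stop("image is smaller than the offset span", call. = FALSE)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  i <- img[rs, cs, drop = FALSE]
  j <- img[rs + dr, cs + dc, drop = FALSE]
  counts <- tabulate(as.integer(i) * levels + as.integer(j) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' Haralick-style features of a co-occurrence matrix
#'
#' Four statistics of a normalised GLCM `P`:
#' contrast `sum (i-j)^2 P_ij`; correlation
#' `(sum i j P_ij - mu_x mu_y) / (sigma_x sigma_y)` with moments from the
#' marginal distributions; energy `sum P_ij^2`; homogeneity
#' `sum P_ij / (1 + (i-j)^2)`. Correlation is `NA` (undefined) when either
#' marginal variance is zero, e.g. for a constant image.
#'
#' @param P Normalised co-occurrence matrix.
#' @return Named numeric vector `c(contrast, correlation, energy,
#'   homogeneity)`.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8)
    stop("P must be a normalised co-occurrence matrix", call. = FALSE)
  g <- seq_len(nrow(P)) - 1
  dif <- outer(g, g, "-")
  contrast <- sum(dif^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + dif^2))
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(g * px); muy <- sum(g * py)
  sx <- sqrt(sum((g - mux)^2 * px)); sy <- sqrt(sum((g - muy)^2 * py))
  correlation <- if (sx * sy == 0) NA_real_ else
    (sum(outer(g, g) * P) - mux * muy) / (sx * sy)
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

.glcm_angles <- data.frame(
  angle = c(0L, 45L, 90L, 135L),
  offset_r = c(0L, -1L, -1L, -1L),
  offset_c = c(1L, 1L, 0L, -1L))

#' GLCM feature table over four angles and two quantisation depths
#'
#' Computes the four [glcm_features()] at offsets `(0,1)`, `(-1,1)`,
#' `(-1,0)`, `(-1,-1)` (0/45/90/135 degrees) for 128 and 256 gray levels:
#' an 8-row table (levels x angle) of contrast, correlation, energy and
#' homogeneity.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param levels Quantisation depths to report.
#' @param symmetric Passed to [glcm()].
#' @return A data frame with columns `levels`, `angle`, `offset_r`,
#'   `offset_c`, `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_feature_table <- function(img, levels = c(128L, 256L), symmetric = FALSE) {
  img <- as_gray_matrix(img)
  rows <- lapply(levels, function(L) {
    q <- quantize(img, L)
    do.call(rbind, lapply(seq_len(nrow(.glcm_angles)), function(k) {
      off <- c(.glcm_angles$offset_r[k], .glcm_angles$offset_c[k])
      f <- glcm_features(glcm(q, off, L, symmetric = symmetric))
      data.frame(levels = L, angle = .glcm_angles$angle[k],
                 offset_r = off[1], offset_c = off[2],
                 contrast = f["contrast"], correlation = f["correlation"],
                 energy = f["energy"], homogeneity = f["homogeneity"],
                 row.names = NULL)
    }))
  })
  do.call(rbind, rows)
}

#' Flatten a GLCM feature table into one feature vector
#'
#' Concatenates the four features over all rows of [glcm_feature_table()]
#' (undefined correlations become 0), giving the fixed-length descriptor the
#' classifier consumes.
#'
#' @inheritParams glcm_feature_table
#' @return Named numeric vector of length `8 * 4` for the default depths.
#' @export
glcm_feature_vector <- function(img, levels = c(128L, 256L), symmetric = FALSE) {
  tab <- glcm_feature_table(img, levels = levels, symmetric = symmetric)
  feats <- as.matrix(tab[, c("contrast", "correlation", "energy", "homogeneity")])
  feats[is.na(feats)] <- 0
  out <- as.numeric(t(feats))
  names(out) <- paste(rep(paste0("L", tab$levels, "_a", tab$angle), each = 4),
                      c("contrast", "correlation", "energy", "homogeneity"),
                      sep = "_")
  out
}
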