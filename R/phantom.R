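#' Specify a synthetic brain phantom
#'
#' A phantom is a 2-D, 8-bit style grayscale image made of three nested
#' regions of constant intensity -- background, an elliptical "brain", and a
#' compact disk-shaped "tumour" that is the brightest class -- together with
#' an exact binary ground-truth mask of the tumour pixels. Phantoms stand in
#' for clinical MRI slices so that every pipeline stage can be exercised
#' against known truth.
#'
#' The tumour centre is drawn (reproducibly, from `seed`) uniformly inside the
#' brain ellipse shrunk by the tumour radius plus a two-pixel margin, so the
#' blob always lies fully inside the brain.
#'
#' @param height,width Image dimensions in pixels (each >= 32).
#' @param tissue_means Numeric vector of three strictly increasing intensities
#'   in `[0, 255]`: background, brain tissue, tumour.
#' @param tumour_radius Tumour disk radius in pixels; must be smaller than a
#'   quarter of the shorter image side.
#' @param noise_sigma Standard deviation of additive Gaussian noise, recorded
#'   in the spec and applied by downstream helpers (not by [make_phantom()],
#'   which always renders the noiseless image).
#' @param block_quality Optional JPEG-style quality (1--100) used by
#'   [add_blockiness()]; `NULL` means no blocking stage.
#' @param seed Integer seed controlling tumour placement (and, downstream, the
#'   noise realisation).
#' @return An object of class `"phantom_spec"`.
#' @seealso [make_phantom()], [add_noise()], [add_blockiness()]
#' @export
#' @examples
#' spec <- phantom_spec(64, 64, tissue_means = c(0, 120, 230), tumour_radius = 8)
#' ph <- make_phantom(spec)
#' table(ph$image)
phantom_spec <- function(height = 96L, width = 96L,
                         tissue_means = c(20, 120, 230),
                         tumour_radius = 10,
                         noise_sigma = 0,
                         block_quality = NULL,
                         seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 32L || width < 32L)
    stop("phantom dimensions must be at least 32x32", call. = FALSE)
  if (length(tissue_means) != 3L || any(diff(tissue_means) <= 0))
    stop("tissue_means must be three strictly increasing intensities", call. = FALSE)
  if (any(tissue_means < 0) || any(tissue_means > 255))
    stop("tissue_means must lie in [0, 255]", call. = FALSE)
  if (tumour_radius <= 0 || tumour_radius >= min(height, width) / 4)
    stop("tumour_radius must be positive and below min(height, width)/4", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  if (!is.null(block_quality)) {
    block_quality <- as.integer(block_quality)
    if (block_quality < 1L || block_quality > 100L)
      stop("block_quality must be in 1..100", call. = FALSE)
  }
  structure(
    list(height = height, width = width,
         tissue_means = as.numeric(tissue_means),
         tumour_radius = as.numeric(tumour_radius),
         noise_sigma = as.numeric(noise_sigma),
         block_quality = block_quality,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %dx%d, tissue means (%s), tumour radius %g px\n",
              x$height, x$width, paste(x$tissue_means, collapse = ", "),
              x$tumour_radius))
  cat(sprintf("  noise sigma %g, block quality %s, seed %d\n",
              x$noise_sigma,
              if (is.null(x$block_quality)) "none" else x$block_quality,
              x$seed))
  invisible(x)
}

#' Render a noiseless phantom image and its ground-truth tumour mask
#'
#' Renders the three-region geometry of a [phantom_spec()]: background at the
#' first tissue mean, an axis-aligned brain ellipse at the second, and a
#' tumour disk at the third (brightest). The returned image is exactly
#' piecewise constant; noise and compression artifacts are added separately by
#' [add_noise()] and [add_blockiness()] so that the clean reference remains
#' available for image-quality metrics.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `image` (numeric matrix, values drawn from
#'   `tissue_means`), `mask` (logical matrix, `TRUE` exactly on tumour
#'   pixels), `labels` (integer matrix of region labels 0 = background,
#'   1 = brain, 2 = tumour), `tumour_center` (x/y in pixel coordinates) and
#'   `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- 0.44 * w   # ellipse semi-axis along columns
  b <- 0.46 * h   # along rows
  r <- spec$tumour_radius

  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  in_brain <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1

  # tumour centre: uniform inside the ellipse shrunk by (r + 2) px margin
  rng <- local_rng(spec$seed)
  shrink_a <- a - r - 2; shrink_b <- b - r - 2
  if (shrink_a <= 0 || shrink_b <= 0)
    stop("tumour_radius too large for the brain ellipse", call. = FALSE)
  repeat {
    u <- rng$runif(2, -1, 1)
    if (u[1]^2 + u[2]^2 <= 1) break
  }
  tx <- cx + u[1] * shrink_a
  ty <- cy + u[2] * shrink_b
  in_tumour <- (col - tx)^2 + (row - ty)^2 <= r^2

  labels <- matrix(0L, h, w)
  labels[in_brain] <- 1L
  labels[in_tumour] <- 2L
  img <- matrix(spec$tissue_means[1], h, w)
  img[labels == 1L] <- spec$tissue_means[2]
  img[labels == 2L] <- spec$tissue_means[3]

  list(image = img, mask = in_tumour, labels = labels,
       tumour_center = c(x = tx, y = ty), spec = spec)
}

#' Add clipped Gaussian noise to a grayscale image
#'
#' Adds zero-mean Gaussian noise of standard deviation `sigma` and clips the
#' result to `[0, 255]`. `sigma = 0` returns the input unchanged.
#'
#' @param img Numeric matrix with values in `[0, 255]`.
#' @param sigma Noise standard deviation (>= 0), in intensity units.
#' @param seed Integer seed for the noise realisation.
#' @return Numeric matrix of the same shape, values in `[0, 255]`.
#' @export
add_noise <- function(img, sigma, seed = 1L) {
  stopifnot(is.matrix(img))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(img)
  rng <- local_rng(seed)
  noisy <- img + matrix(rng$rnorm(length(img), sd = sigma), nrow(img), ncol(img))
  clip255(noisy)
}

# 8x8 DCT-II basis, orthonormal
dct_matrix <- function(n = 8L) {
  k <- 0:(n - 1)
  M <- sqrt(2 / n) * cos(outer(k, k + 0.5) * pi / n)
  M[1, ] <- sqrt(1 / n)
  M
}

# Standard JPEG luminance quantisation table (Annex K), scaled by quality.
jpeg_luma_qtable <- function(quality) {
  base <- matrix(c(
    16, 11, 10, 16, 24, 40, 51, 61,
    12, 12, 14, 19, 26, 58, 60, 55,
    14, 13, 16, 24, 40, 57, 69, 56,
    14, 17, 22, 29, 51, 87, 80, 62,
    18, 22, 37, 56, 68, 109, 103, 77,
    24, 35, 55, 64, 81, 104, 113, 92,
    49, 64, 78, 87, 103, 121, 120, 101,
    72, 92, 95, 98, 112, 100, 103, 99), 8, 8, byrow = TRUE)
  s <- if (quality < 50) 5000 / quality else 200 - 2 * quality
  q <- floor((base * s + 50) / 100)
  pmax(q, 1)
}

#' Simulate JPEG-style blocking artifacts
#'
#' Quantises the DCT coefficients of each `block` x `block` tile with the
#' standard luminance quantisation table scaled by `quality`, producing the
#' visible intensity steps at block boundaries that the deblocking stage of
#' the denoiser is designed to remove. Images whose sides are not multiples of
#' `block` are padded by edge replication internally and cropped back.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param block Block side in pixels (default 8; must be >= 2). Quantisation
#'   tables other than 8x8 are obtained by bilinear resampling of the standard
#'   table.
#' @param quality Integer 1--100; 100 is a near-identity, low values produce
#'   strong blockiness.
#' @return Numeric matrix of the same shape, values in `[0, 255]`.
#' @export
add_blockiness <- function(img, block = 8L, quality = 50L) {
  stopifnot(is.matrix(img))
  block <- as.integer(block)
  if (block < 2L) stop("block must be at least 2", call. = FALSE)
  quality <- as.integer(quality)
  if (quality < 1L || quality > 100L) stop("quality must be in 1..100", call. = FALSE)
  if (quality == 100L) return(img)   # all quantisation steps collapse to 1

  h <- nrow(img); w <- ncol(img)
  H <- ceiling(h / block) * block
  W <- ceiling(w / block) * block
  pad <- img[c(seq_len(h), rep(h, H - h)), c(seq_len(w), rep(w, W - w)), drop = FALSE]

  D <- dct_matrix(block)
  q8 <- jpeg_luma_qtable(quality)
  Q <- if (block == 8L) q8 else resample_bilinear(q8, block, block)

  out <- pad
  for (bi in seq_len(H / block)) {
    rs <- ((bi - 1) * block + 1):(bi * block)
    for (bj in seq_len(W / block)) {
      cs <- ((bj - 1) * block + 1):(bj * block)
      tile <- pad[rs, cs] - 128
      coef <- D %*% tile %*% t(D)
      coef <- round(coef / Q) * Q
      out[rs, cs] <- t(D) %*% coef %*% D + 128
    }
  }
  clip255(out[seq_len(h), seq_len(w), drop = FALSE])
}

# Bilinear resampling of a small matrix to nr x nc (used only for non-8 blocks)
resample_bilinear <- function(m, nr, nc) {
  sr <- seq(1, nrow(m), length.out = nr)
  sc <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(sr), nrow(m) - 1); c0 <- pmin(floor(sc), ncol(m) - 1)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- (1 - fr[i]) * (1 - fc[j]) * m[r0[i], c0[j]] +
      fr[i] * (1 - fc[j]) * m[r0[i] + 1, c0[j]] +
      (1 - fr[i]) * fc[j] * m[r0[i], c0[j] + 1] +
      fr[i] * fc[j] * m[r0[i] + 1, c0[j] + 1]
  }
  out
}
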