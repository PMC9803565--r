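#' Bilateral filter parameters
#'
#' The bilateral filter smooths with the product of a spatial Gaussian
#' (scale `sigma_d`, in pixels) and a range Gaussian (scale `sigma_r`, in
#' intensity units), so that only neighbours that are both close and similar
#' contribute. Either scale may be a single number or a per-pixel matrix (as
#' produced by [adapt_params()]).
#'
#' Defaults follow the reference configuration used throughout this package:
#' `sigma_d = 1.8`, an 11x11 window, and `sigma_r` equal to the estimated
#' noise standard deviation (set by the caller).
#'
#' @param sigma_d Spatial scale in pixels (> 0); scalar or matrix.
#' @param sigma_r Range scale in intensity units (> 0); scalar or matrix.
#' @param window Odd window side length (>= 3).
#' @return An object of class `"bilateral_params"`.
#' @export
bilateral_params <- function(sigma_d = 1.8, sigma_r = 10, window = 11L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (any(sigma_d <= 0)) stop("sigma_d must be positive", call. = FALSE)
  if (any(sigma_r <= 0)) stop("sigma_r must be positive", call. = FALSE)
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r, window = window),
            class = "bilateral_params")
}

#' @export
print.bilateral_params <- function(x, ...) {
  fmt <- function(v) if (is.matrix(v))
    sprintf("per-pixel [%.3g..%.3g]", min(v), max(v)) else sprintf("%.3g", v)
  cat(sprintf("Bilateral params: sigma_d %s, sigma_r %s, window %dx%d\n",
              fmt(x$sigma_d), fmt(x$sigma_r), x$window, x$window))
  invisible(x)
}

#' Edge-preserving bilateral filtering
#'
#' Each output pixel is the weighted mean of its window, with weight
#' `exp(-(dr^2+dc^2) / (2 sigma_d^2)) * exp(-(I(q)-I(p))^2 / (2 sigma_r^2))`.
#' A range scale below a discontinuity leaves the discontinuity essentially
#' intact; a range scale above it smooths across it -- the lever the adaptive
#' deblocking stage pulls. At image borders the window is truncated to valid
#' pixels and the weights renormalised.
#'
#' @param img Numeric matrix.
#' @param params A [bilateral_params()] object; `sigma_d` / `sigma_r` may be
#'   per-pixel matrices matching `dim(img)`.
#' @return Filtered matrix of the same shape.
#' @export
#' @examples
#' step <- matrix(rep(c(100, 110), each = 8 * 16), 16, 16)
#' out <- bilateral_filter(step, bilateral_params(sigma_d = 1.8, sigma_r = 2))
#' max(abs(out - step)) < 1   # sigma_r below the step: edge preserved
bilateral_filter <- function(img, params) {
  img <- as_gray_matrix(img)
  stopifnot(inherits(params, "bilateral_params"))
  h <- nrow(img); w <- ncol(img)
  expand <- function(v, what) {
    if (is.matrix(v)) {
      if (!all(dim(v) == dim(img)))
        stop(what, " matrix must match image dimensions", call. = FALSE)
      v
    } else matrix(v, h, w)
  }
  sd2 <- 2 * expand(params$sigma_d, "sigma_d")^2
  sr2 <- 2 * expand(params$sigma_r, "sigma_r")^2
  hw <- (params$window - 1L) %/% 2L

  acc_w <- matrix(0, h, w)
  acc_v <- matrix(0, h, w)
  for (dr in -hw:hw) {
    if (1L - dr > h || h - dr < 1L) next
    r_out <- max(1L, 1L - dr):min(h, h - dr)
    for (dc in -hw:hw) {
      if (1L - dc > w || w - dc < 1L) next
      c_out <- max(1L, 1L - dc):min(w, w - dc)
      nb <- img[r_out + dr, c_out + dc, drop = FALSE]
      cen <- img[r_out, c_out, drop = FALSE]
      wgt <- exp(-(dr * dr + dc * dc) / sd2[r_out, c_out, drop = FALSE] -
                   (nb - cen)^2 / sr2[r_out, c_out, drop = FALSE])
      acc_w[r_out, c_out] <- acc_w[r_out, c_out] + wgt
      acc_v[r_out, c_out] <- acc_v[r_out, c_out] + wgt * nb
    }
  }
  acc_v / acc_w
}

#' Measure intensity discontinuities at compression-block boundaries
#'
#' Probes every block boundary with the central-difference kernel
#' `[-1, 0, 1]` (columns) and its transpose (rows). The response across the
#' boundary between positions `j` and `j+1` is the sum of the two halved
#' probe responses centred at `j` and `j+1`, so a clean step of height `h`
#' reports exactly `h`, while on a smooth ramp boundary responses equal
#' interior ones (no false blockiness).
#'
#' @param img Numeric matrix.
#' @param block Block side in pixels (>= 2); boundaries sit after columns/rows
#'   `block, 2*block, ...`.
#' @details
#' The same probe is also evaluated between every interior column/row pair;
#' the mean interior response is stored as a reference level. Genuine
#' blocking artifacts raise the boundary responses well above it, whereas
#' ordinary image structure (edges, noise) excites boundary and interior
#' positions alike -- the comparison the adaptive filter uses to decide
#' whether an image is blocky at all.
#'
#' @return An object of class `"discontinuity_map"`: `vertical` is an
#'   `nrow x n_vbound` matrix of responses (one column per vertical boundary),
#'   `horizontal` is `n_hbound x ncol`; `v_cols` / `h_rows` give the boundary
#'   positions (boundary after that column/row); `boundary_mean` and
#'   `interior_median` summarise the probe at boundary and non-boundary
#'   positions (the interior excludes positions adjacent to boundaries,
#'   whose probes cross the boundary step).
#' @export
detect_block_discontinuity <- function(img, block = 8L) {
  img <- as_gray_matrix(img)
  block <- as.integer(block)
  if (block < 2L) stop("block must be at least 2", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  clampc <- function(j) pmin(pmax(j, 1L), w)
  clampr <- function(i) pmin(pmax(i, 1L), h)
  resp_v <- function(j)
    abs(img[, clampc(j + 1L)] - img[, clampc(j - 1L)]) / 2 +
    abs(img[, clampc(j + 2L)] - img[, clampc(j)]) / 2
  resp_h <- function(i)
    abs(img[clampr(i + 1L), ] - img[clampr(i - 1L), ]) / 2 +
    abs(img[clampr(i + 2L), ] - img[clampr(i), ]) / 2

  v_cols <- seq(block, w - 1L, by = block)
  vertical <- matrix(0, h, length(v_cols))
  for (k in seq_along(v_cols)) vertical[, k] <- resp_v(v_cols[k])
  h_rows <- seq(block, h - 1L, by = block)
  horizontal <- matrix(0, length(h_rows), w)
  for (k in seq_along(h_rows)) horizontal[k, ] <- resp_h(h_rows[k])

  # interior reference: exclude positions within 1 px of a boundary, whose
  # probe responses pick up part of the boundary step itself
  far_from <- function(pos, bnd) pos[vapply(pos, function(p)
    length(bnd) == 0L || min(abs(p - bnd)) > 1L, TRUE)]
  int_v <- far_from(seq_len(w - 1L), v_cols)
  int_h <- far_from(seq_len(h - 1L), h_rows)
  interior <- c(vapply(int_v, resp_v, numeric(h)),
                vapply(int_h, resp_h, numeric(w)))
  # without interior positions (block too small for the guard zone) there is
  # no reference to compare against, and no boundary can be called blocky
  interior_median <- if (length(interior)) stats::median(interior) else Inf

  structure(list(vertical = vertical, v_cols = v_cols,
                 horizontal = horizontal, h_rows = h_rows,
                 boundary_mean = mean(c(vertical, horizontal)),
                 interior_median = interior_median,
                 block = block, dim = c(h, w)),
            class = "discontinuity_map")
}

#' Decide whether an image shows blocking artifacts
#'
#' `TRUE` when at least one block boundary's median probe response clearly
#' exceeds the interior reference of the [detect_block_discontinuity()] map.
#' The multiresolution denoiser evaluates this once at full resolution --
#' where block boundaries actually live -- and only then enables the
#' deblocking `sigma_r` adaptation at every scale.
#'
#' @param disc A `"discontinuity_map"`, or an image matrix (then `block` is
#'   used to compute the map first).
#' @param block Block size when `disc` is an image.
#' @return Logical flag.
#' @export
is_blocky <- function(disc, block = 8L) {
  if (!inherits(disc, "discontinuity_map"))
    disc <- detect_block_discontinuity(disc, block)
  thr <- 1.5 * disc$interior_median + 1e-12
  any(apply(disc$vertical, 2, stats::median) > thr) ||
    any(apply(disc$horizontal, 1, stats::median) > thr)
}

#' Mean absolute step across block boundaries
#'
#' Summary statistic of a [detect_block_discontinuity()] map: the mean of all
#' boundary responses. Used to quantify blockiness before and after
#' deblocking.
#'
#' @param disc A `"discontinuity_map"`, or an image matrix (then `block` is
#'   used to compute the map first).
#' @param block Block size when `disc` is an image.
#' @return Mean boundary response (intensity units).
#' @export
boundary_step_mean <- function(disc, block = 8L) {
  if (!inherits(disc, "discontinuity_map"))
    disc <- detect_block_discontinuity(disc, block)
  mean(c(disc$vertical, disc$horizontal))
}

#' Local texture activity
#'
#' Population standard deviation of intensity over a sliding window, the
#' smoothness signal that drives the spatial-scale adaptation: high activity
#' means real texture that must not be over-smoothed. Windows are truncated
#' at image borders.
#'
#' @param img Numeric matrix.
#' @param window Odd window side length.
#' @return Matrix of per-pixel local standard deviations.
#' @export
texture_activity <- function(img, window = 7L) {
  img <- as_gray_matrix(img)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  hw <- (window - 1L) %/% 2L
  box <- function(m) {
    # sum over the clamped window, via padded cumulative sums
    cs <- apply(rbind(0, m), 2, cumsum)
    hs <- nrow(m)
    top <- pmax(seq_len(hs) - hw - 1L, 0L) + 1L
    bot <- pmin(seq_len(hs) + hw, hs) + 1L
    v <- cs[bot, , drop = FALSE] - cs[top, , drop = FALSE]
    cs2 <- t(apply(cbind(0, v), 1, cumsum))
    ws <- ncol(m)
    lft <- pmax(seq_len(ws) - hw - 1L, 0L) + 1L
    rgt <- pmin(seq_len(ws) + hw, ws) + 1L
    cs2[, rgt, drop = FALSE] - cs2[, lft, drop = FALSE]
  }
  n <- box(matrix(1, nrow(img), ncol(img)))
  s1 <- box(img)
  s2 <- box(img^2)
  mu <- s1 / n
  sqrt(pmax(s2 / n - mu^2, 0))
}

#' Adapt bilateral parameters to block boundaries and texture
#'
#' Builds per-pixel bilateral scales from two detectors. The range scale
#' `sigma_r` is raised at block boundaries to at least the measured
#' discontinuity (times a 1.1 safety factor) -- a range scale below the step
#' cannot remove it -- and decays linearly back to the base value over a
#' 2-pixel band. Two gates keep the bump honest: a boundary is only treated
#' as a block discontinuity when its median response clearly exceeds the
#' map's interior reference (sparse anatomical edges and plain noise excite
#' boundary and interior positions alike), and individual steps must exceed
#' twice the noise level. The spatial scale `sigma_d` shrinks where texture activity
#' is high (avoiding over-smoothing) and stays at its base value on smooth
#' regions, via `sigma_d = base * clamp(s0 / (s0 + activity), 0.3, 1)` with
#' `s0` the noise-level estimate.
#'
#' @param disc A [detect_block_discontinuity()] map.
#' @param texture A [texture_activity()] matrix with the image's geometry.
#' @param base A [bilateral_params()] with scalar scales.
#' @param noise_sigma Noise-level estimate `s0` (>= 0); defaults to the base
#'   range scale.
#' @param deblock Apply the boundary-driven `sigma_r` bumps; set `FALSE`
#'   (e.g. when [is_blocky()] is `FALSE` at full resolution) to keep only
#'   the texture-driven `sigma_d` adaptation.
#' @return A `"bilateral_params"` object with per-pixel `sigma_d` and
#'   `sigma_r` matrices.
#' @export
adapt_params <- function(disc, texture, base, noise_sigma = NULL,
                         deblock = TRUE) {
  stopifnot(inherits(disc, "discontinuity_map"),
            inherits(base, "bilateral_params"))
  h <- disc$dim[1]; w <- disc$dim[2]
  if (!is.matrix(texture) || !all(dim(texture) == c(h, w)))
    stop("texture map must match the discontinuity map's geometry", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- base$sigma_r
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)

  base_r <- base$sigma_r
  sigma_r <- matrix(base_r, h, w)
  # a boundary counts as a block discontinuity only when its typical (median)
  # response clearly exceeds the interior reference; sparse edge crossings
  # and plain noise excite boundary and interior positions alike and leave
  # the medians comparable, so no bump is applied there
  active <- function(resp)
    stats::median(resp) > 1.5 * disc$interior_median + 1e-12
  floor_ <- 2 * noise_sigma
  bump <- function(cur, target, weight) pmax(cur, base_r + (target - base_r) * weight)
  gate <- function(step) ifelse(step > floor_, pmax(base_r, 1.1 * step), base_r)
  # weight 1 at the two boundary-adjacent pixels, 1/2 one pixel out, 0 beyond
  for (k in if (deblock) seq_along(disc$v_cols) else integer(0)) {
    j <- disc$v_cols[k]
    if (!active(disc$vertical[, k])) next
    tgt <- gate(disc$vertical[, k])
    for (d in 0:1) {
      wgt <- 1 - d / 2
      for (jj in c(j - d, j + 1L + d)) {
        if (jj >= 1L && jj <= w)
          sigma_r[, jj] <- bump(sigma_r[, jj], tgt, wgt)
      }
    }
  }
  for (k in if (deblock) seq_along(disc$h_rows) else integer(0)) {
    i <- disc$h_rows[k]
    if (!active(disc$horizontal[k, ])) next
    tgt <- gate(disc$horizontal[k, ])
    for (d in 0:1) {
      wgt <- 1 - d / 2
      for (ii in c(i - d, i + 1L + d)) {
        if (ii >= 1L && ii <= h)
          sigma_r[ii, ] <- bump(sigma_r[ii, ], tgt, wgt)
      }
    }
  }

  factor <- ifelse(texture == 0, 1, noise_sigma / (noise_sigma + texture))
  sigma_d <- base$sigma_d * pmin(pmax(factor, 0.3), 1)

  bilateral_params(sigma_d = sigma_d, sigma_r = sigma_r, window = base$window)
}
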