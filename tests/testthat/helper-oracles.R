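# Independent brute-force oracles used to cross-check the vectorised
# implementations. These are deliberately written as plain double loops.

# Bilateral filter: direct weighted sum over the (truncated) window.
oracle_bilateral <- function(img, sigma_d, sigma_r, window) {
  h <- nrow(img); w <- ncol(img)
  hw <- (window - 1) %/% 2
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    num <- 0; den <- 0
    for (rr in max(1, r - hw):min(h, r + hw)) {
      for (cc in max(1, c - hw):min(w, c + hw)) {
        wt <- exp(-((rr - r)^2 + (cc - c)^2) / (2 * sigma_d^2)) *
          exp(-(img[rr, cc] - img[r, c])^2 / (2 * sigma_r^2))
        num <- num + wt * img[rr, cc]
        den <- den + wt
      }
    }
    out[r, c] <- num / den
  }
  out
}

# Co-occurrence matrix: explicit loop over every pixel pair.
oracle_glcm <- function(q, dr, dc, levels) {
  P <- matrix(0, levels, levels)
  h <- nrow(q); w <- ncol(q)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w)
      P[q[r, c] + 1, q[r2, c2] + 1] <- P[q[r, c] + 1, q[r2, c2] + 1] + 1
  }
  P / sum(P)
}

# GLCM features: direct summation from the definition.
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  contrast <- 0; energy <- 0; homog <- 0; sij <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    energy <- energy + P[i, j]^2
    homog <- homog + P[i, j] / (1 + (i - j)^2)
    sij <- sij + (i - 1) * (j - 1) * P[i, j]
  }
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
  vx <- sum(((0:(L - 1)) - mux)^2 * px); vy <- sum(((0:(L - 1)) - muy)^2 * py)
  corr <- if (vx * vy == 0) NA_real_ else (sij - mux * muy) / sqrt(vx * vy)
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog)
}

# Best crisp 2-clustering of a small 1-D point set by full enumeration.
oracle_best_2partition <- function(x) {
  n <- length(x)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    obj <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    if (obj < best_obj) { best_obj <- obj; best <- g }
  }
  best
}

# Pixel count of a rasterised disk by direct enumeration.
oracle_disk_area <- function(cx, cy, r, h, w) {
  n <- 0
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((j - cx)^2 + (i - cy)^2 <= r^2) n <- n + 1
  n
}
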