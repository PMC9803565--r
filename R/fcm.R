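#' Euclidean point-to-centre distances
#'
#' Distance matrix `d_ij = ||x_i - z_j||` between data points and cluster
#' centres, the quantity the fuzzy memberships are built from.
#'
#' @param points Numeric matrix (n x d) or vector (treated as n x 1).
#' @param centers Numeric matrix (c x d) or vector.
#' @return An n x c matrix of non-negative distances.
#' @export
fcm_distances <- function(points, centers) {
  points <- as_points(points)
  centers <- as_points(centers)
  if (ncol(points) != ncol(centers))
    stop("points and centers must have the same feature dimension", call. = FALSE)
  d2 <- outer(rowSums(points^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(points)), rowSums(centers^2)) -
    2 * points %*% t(centers)
  sqrt(pmax(d2, 0))
}

as_points <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1) else {
    storage.mode(x) <- "double"
    x
  }
}

#' Fuzzy membership update
#'
#' Memberships `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`; every row sums to
#' one. A point at zero distance from one or more centres splits its
#' membership equally among those centres.
#'
#' @param D Distance matrix (n x c) from [fcm_distances()].
#' @param m Fuzzifier (> 1); larger values give softer partitions.
#' @return An n x c membership matrix with unit row sums.
#' @export
fcm_memberships <- function(D, m = 2) {
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  W <- D^(-2 / (m - 1))
  U <- W / rowSums(W)
  zero <- which(rowSums(D == 0) > 0L)
  for (i in zero) {
    z <- D[i, ] == 0
    U[i, ] <- 0
    U[i, z] <- 1 / sum(z)
  }
  U
}

#' Fuzzy cluster-centre update
#'
#' Membership-weighted means `z_j = sum_i u_ij^m x_i / sum_i u_ij^m`
#' (optionally with per-point multiplicities `weights`, used when clustering
#' binned pixel intensities).
#'
#' @param points Numeric matrix (n x d) or vector.
#' @param U Membership matrix (n x c).
#' @param m Fuzzifier (> 1).
#' @param weights Optional non-negative per-point multiplicities.
#' @return A c x d matrix of centres.
#' @export
fcm_centers <- function(points, U, m = 2, weights = NULL) {
  points <- as_points(points)
  Um <- U^m
  if (!is.null(weights)) Um <- Um * weights
  denom <- colSums(Um)
  if (any(denom <= 0))
    stop("cluster ", which(denom <= 0)[1],
         " has zero total membership; cannot place its centre", call. = FALSE)
  t(Um) %*% points / denom
}

#' Fuzzy c-means objective
#'
#' `J_m = sum_i sum_j u_ij^m ||x_i - z_j||^2`, the quantity both the
#' alternating FCM iteration and the swarm optimiser minimise.
#'
#' @inheritParams fcm_centers
#' @param centers Centre matrix (c x d).
#' @return Non-negative scalar.
#' @export
fcm_objective <- function(points, U, centers, m = 2, weights = NULL) {
  D2 <- fcm_distances(points, centers)^2
  Um <- U^m
  if (!is.null(weights)) Um <- Um * weights
  sum(Um * D2)
}

# J_m evaluated at a centre set with memberships recomputed there: the
# fitness used by the swarm optimiser.
fcm_fitness <- function(points, centers, m = 2, weights = NULL) {
  D <- fcm_distances(points, centers)
  U <- fcm_memberships(D, m)
  Um <- U^m
  if (!is.null(weights)) Um <- Um * weights
  sum(Um * D^2)
}

#' Fuzzy c-means clustering
#'
#' Classical alternating optimisation of the fuzzy objective: membership
#' update, centre update, repeat until the largest membership change falls
#' below `tol` or `max_iter` is reached. Returns a classed fit with the usual
#' accessor methods (`print`, `summary`, `coef`, `fitted`, `predict`,
#' `plot`).
#'
#' @param x Numeric matrix (n x d) or vector of data points.
#' @param centers Number of clusters (>= 2), or an initial c x d centre
#'   matrix.
#' @param m Fuzzifier (> 1); 2 is the conventional default.
#' @param tol Convergence tolerance on `max |U_new - U_old|`.
#' @param max_iter Iteration cap.
#' @param weights Optional per-point multiplicities (e.g. histogram counts).
#' @param seed Integer seed for the random centre initialisation (ignored
#'   when `centers` is a matrix).
#' @return An object of class `"fcm"`: `centers`, `U` (memberships),
#'   `objective` (final `J_m`), `J_trace`, `iterations`, `converged`, `m`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 10, 2), rnorm(50, 200, 2))
#' fit <- fcm(x, centers = 2, seed = 1)
#' sort(coef(fit)[, 1])  # close to 10 and 200
fcm <- function(x, centers = 2L, m = 2, tol = 1e-5, max_iter = 100L,
                weights = NULL, seed = 1L) {
  pts <- as_points(x)
  n <- nrow(pts)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights >= 0))
  }
  if (is.matrix(centers) || (is.numeric(centers) && length(centers) > 1)) {
    Z <- as_points(centers)
    c_ <- nrow(Z)
  } else {
    c_ <- as.integer(centers)
    if (c_ < 2L) stop("need at least 2 clusters", call. = FALSE)
    if (n <= c_) stop("need more points than clusters", call. = FALSE)
    uniq <- unique(pts)
    if (nrow(uniq) < c_)
      stop("data has fewer than ", c_, " distinct points; ",
           "degenerate input cannot support ", c_, " clusters", call. = FALSE)
    rng <- local_rng(seed)
    Z <- uniq[rng$sample_int(nrow(uniq), c_), , drop = FALSE]
  }
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)

  U_old <- NULL
  J_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- fcm_distances(pts, Z)
    U <- fcm_memberships(D, m)
    Z <- fcm_centers(pts, U, m, weights)
    Um <- U^m
    if (!is.null(weights)) Um <- Um * weights
    J_trace[iter] <- sum(Um * fcm_distances(pts, Z)^2)
    if (!is.null(U_old) && max(abs(U - U_old)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    U_old <- U
  }

  structure(list(centers = Z, U = U, m = m,
                 objective = J_trace[iter], J_trace = J_trace,
                 iterations = iter, converged = converged,
                 weights = weights, n = n, d = ncol(pts),
                 call = match.call()),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means fit: %d clusters, m = %g, %d points (%d-D)\n",
              nrow(x$centers), x$m, x$n, x$d))
  cat(sprintf("  J_m = %.6g after %d iteration(s)%s\n", x$objective,
              x$iterations, if (x$converged) " (converged)" else ""))
  cat("Centers:\n")
  print(round(x$centers, 4))
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  lab <- apply(object$U, 1, which.max)
  sizes <- tabulate(lab, nbins = nrow(object$centers))
  out <- list(fit = object, sizes = sizes,
              mean_max_membership = mean(apply(object$U, 1, max)))
  class(out) <- "summary.fcm"
  out
}

#' @export
print.summary.fcm <- function(x, ...) {
  print(x$fit)
  cat("Hard-label cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("Mean maximal membership: %.3f\n", x$mean_max_membership))
  invisible(x)
}

#' @export
coef.fcm <- function(object, ...) object$centers

#' @export
fitted.fcm <- function(object, ...) {
  # max-membership hard labels; ties resolved to the lowest cluster index
  apply(object$U, 1, which.max)
}

#' @export
predict.fcm <- function(object, newdata,
                        type = c("membership", "label"), ...) {
  type <- match.arg(type)
  U <- fcm_memberships(fcm_distances(as_points(newdata), object$centers),
                       object$m)
  if (type == "membership") U else apply(U, 1, which.max)
}

#' @export
plot.fcm <- function(x, ...) {
  graphics::plot(seq_along(x$J_trace), x$J_trace, type = "b",
                 xlab = "iteration", ylab = expression(J[m]),
                 main = "Fuzzy c-means objective", ...)
  invisible(x)
}
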