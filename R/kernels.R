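#' Specify an SVM kernel
#'
#' The five kernel families compared for tumour classification:
#' \describe{
#'   \item{linear}{`<x, y>`}
#'   \item{polynomial}{`(<x, y> + 1)^degree`}
#'   \item{grbf}{Gaussian RBF `exp(-||x - y||^2 / (2 sigma^2))`}
#'   \item{erbf}{exponential RBF `exp(-||x - y|| / (2 sigma^2))` (unsquared
#'     distance)}
#'   \item{anova}{`(sum_k exp(-sigma (x_k - y_k)^2))^degree`}
#' }
#' Both radial families evaluate to 1 at `x = y`.
#'
#' @param family One of `"linear"`, `"polynomial"`, `"grbf"`, `"erbf"`,
#'   `"anova"`.
#' @param degree Polynomial / ANOVA degree (typically 1--5).
#' @param sigma Scale for the radial and ANOVA families (typically 1--5).
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "grbf", "erbf", "anova"),
                        degree = 3L, sigma = 1) {
  family <- match.arg(family)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be a positive integer", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(family = family, degree = degree, sigma = sigma),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
    linear = "",
    polynomial = sprintf(" (degree %d)", x$degree),
    grbf = ,
    erbf = sprintf(" (sigma %g)", x$sigma),
    anova = sprintf(" (degree %d, sigma %g)", x$degree, x$sigma))
  cat("Kernel:", x$family, extra, "\n", sep = "")
  invisible(x)
}

#' Evaluate a kernel on a pair of feature vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,y Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
#' @examples
#' k <- kernel_spec("grbf", sigma = 2)
#' kernel_eval(k, c(0, 0), c(2, 0))  # ||x-y|| = sigma: exp(-1/2)
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  switch(spec$family,
    linear = sum(x * y),
    polynomial = (sum(x * y) + 1)^spec$degree,
    grbf = exp(-sum((x - y)^2) / (2 * spec$sigma^2)),
    erbf = exp(-sqrt(sum((x - y)^2)) / (2 * spec$sigma^2)),
    anova = (sum(exp(-spec$sigma * (x - y)^2)))^spec$degree)
}

#' Kernel (Gram) matrix between two sample sets
#'
#' @param spec A [kernel_spec()].
#' @param X Numeric matrix, one sample per row.
#' @param Y Optional second sample matrix (defaults to `X`).
#' @return `nrow(X)` x `nrow(Y)` Gram matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as_points(X); Y <- as_points(Y)
  if (ncol(X) != ncol(Y))
    stop("X and Y must have the same dimension", call. = FALSE)
  ip <- X %*% t(Y)
  # squared distances accumulated per dimension: free of the cancellation
  # the ||x||^2 + ||y||^2 - 2<x,y> shortcut suffers at small separations
  d2mat <- function() {
    d2 <- matrix(0, nrow(X), nrow(Y))
    for (k in seq_len(ncol(X)))
      d2 <- d2 + outer(X[, k], Y[, k], "-")^2
    d2
  }
  switch(spec$family,
    linear = ip,
    polynomial = (ip + 1)^spec$degree,
    grbf = exp(-d2mat() / (2 * spec$sigma^2)),
    erbf = exp(-sqrt(d2mat()) / (2 * spec$sigma^2)),
    anova = {
      K <- matrix(0, nrow(X), nrow(Y))
      for (k in seq_len(ncol(X)))
        K <- K + exp(-spec$sigma * outer(X[, k], Y[, k], "-")^2)
      K^spec$degree
    })
}
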