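# Internal helpers shared across modules.

clip255 <- function(x) pmin(pmax(x, 0), 255)

# A self-contained RNG stream: draws are a pure function of `seed` and do not
# disturb (or depend on) the caller's global RNG state.
local_rng <- function(seed) {
  state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old))
      rm(".Random.seed", envir = globalenv())
    else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    sample_int = function(n, size, replace = FALSE)
      draw(base::sample.int, n, size, replace = replace),
    derive = function(k) draw(function() base::sample.int(.Machine$integer.max - 1L, k))
  )
}

as_gray_matrix <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix (grayscale image)", call. = FALSE)
  img
}
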