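# Guaranteed-convergence particle swarm optimisation (GCPSO) over fuzzy
# cluster-centre sets, hybridised with FCM inner refinement. Each particle's
# position is a flattened c x d centre matrix; fitness is the fuzzy
# objective J_m with memberships recomputed at the particle's centres.

#' One particle-velocity update (GCPSO / canonical PSO)
#'
#' Non-best particles follow the canonical two-attractor rule
#' `v' = omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`. The particle that
#' owns the global best instead uses the guaranteed-convergence rule
#' `v' = -x + gbest + omega v + rho (1 - 2 r)`, so its next position
#' `x + v'` samples the box `gbest + omega v +/- rho` around the incumbent
#' optimum -- the mechanism that prevents total stagnation when all
#' attractors coincide.
#'
#' @param position,velocity,pbest,gbest Numeric vectors of equal length.
#' @param omega Inertia weight.
#' @param c1,c2 Cognitive and social acceleration constants (ignored for the
#'   best particle).
#' @param rho Current search-box radius `rho(t)` (best particle only).
#' @param is_best `TRUE` for the particle owning the global best.
#' @param r Uniform(0,1) draws: for the best particle one draw per
#'   coordinate; otherwise a list/vector supplying `r1` and `r2` per
#'   coordinate.
#' @return The updated velocity vector.
#' @export
#' @examples
#' # best particle: x = 5, gbest = 3, omega*v = 1, rho = 2, r = 0.25
#' gcpso_velocity(5, 1, 5, 3, omega = 1, rho = 2, is_best = TRUE, r = 0.25)
#' # -5 + 3 + 1 + 2 * (1 - 0.5) = 0
gcpso_velocity <- function(position, velocity, pbest, gbest,
                           omega = 0.72, c1 = 1.49, c2 = 1.49,
                           rho = 1, is_best = FALSE, r) {
  if (is_best) {
    -position + gbest + omega * velocity + rho * (1 - 2 * r)
  } else {
    r1 <- if (is.list(r)) r[[1]] else r[seq_along(position)]
    r2 <- if (is.list(r)) r[[2]] else r[seq_along(position) + length(position)]
    omega * velocity + c1 * r1 * (pbest - position) + c2 * r2 * (gbest - position)
  }
}

#' Adapt the GCPSO search radius from success/failure streaks
#'
#' Tracks consecutive successes (global best improved) and failures. A
#' success zeroes the failure counter and vice versa. After more than `sc`
#' consecutive successes the radius `rho` doubles; after more than `fc`
#' consecutive failures it halves; the triggering counter resets. The
#' thresholds default to `sc = 15`, `fc = 5`, suited to the few-iteration,
#' high-dimensional searches this package runs. `rho` is clamped to
#' `[rho_min, rho_max]`.
#'
#' @param rho Current radius (> 0).
#' @param success_count,failure_count Current streak counters.
#' @param improved `TRUE` if the global best improved this generation.
#' @param sc,fc Success / failure streak thresholds.
#' @param rho_min,rho_max Clamp bounds (default: tiny floor, no ceiling).
#' @return `list(rho, success_count, failure_count)`.
#' @export
#' @examples
#' s <- list(rho = 1, success_count = 0, failure_count = 0)
#' for (i in 1:16) s <- rho_update(s$rho, s$success_count, s$failure_count, TRUE)
#' s$rho  # 2
rho_update <- function(rho, success_count = 0L, failure_count = 0L, improved,
                       sc = 15L, fc = 5L, rho_min = 1e-10, rho_max = Inf) {
  stopifnot(rho > 0)
  if (improved) {
    failure_count <- 0L
    success_count <- success_count + 1L
  } else {
    success_count <- 0L
    failure_count <- failure_count + 1L
  }
  if (success_count > sc) {
    rho <- rho * 2
    success_count <- 0L
  } else if (failure_count > fc) {
    rho <- rho / 2
    failure_count <- 0L
  }
  list(rho = min(max(rho, rho_min), rho_max),
       success_count = success_count, failure_count = failure_count)
}

#' Hybrid GCPSO-FCM clustering
#'
#' A population of particles, each encoding a full set of cluster centres,
#' explores the fuzzy objective `J_m` under GCPSO dynamics; every
#' `refine_every` generations each particle is additionally refined by a few
#' FCM alternating iterations, and the refined centres replace the particle's
#' position whenever they improve its fitness (Lamarckian update). The swarm
#' escapes poor local minima that plain FCM can fall into, while the FCM
#' moves give fast local convergence. Terminates when the global best has
#' not improved for `stagnation` generations, or after `max_gen`
#' generations; the returned partition is read off the global best.
#'
#' @inheritParams fcm
#' @param centers Number of clusters (>= 2).
#' @param pop Swarm size (>= 2).
#' @param omega Inertia weight.
#' @param c1,c2 Acceleration constants for the canonical-rule particles.
#' @param rho0 Initial GCPSO search radius.
#' @param sc,fc Success / failure thresholds for [rho_update()].
#' @param max_gen Generation cap.
#' @param stagnation Stop after this many generations without global-best
#'   improvement.
#' @param refine_every Run FCM refinement every this many generations.
#' @param inner_iters FCM iterations per refinement.
#' @param seed Integer seed; the whole fit is a pure function of data + seed.
#' @return An object of class `c("gcpso_fcm", "fcm")` with the [fcm()]
#'   components plus `gbest_trace` (per-generation global-best fitness,
#'   non-increasing), `rho_trace`, and `generations`.
#' @export
#' @examples
#' set.seed(7)
#' x <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 8), ncol = 2))
#' fit <- gcpso_fcm(x, centers = 2, seed = 7)
#' coef(fit)
gcpso_fcm <- function(x, centers = 3L, m = 2, pop = 20L,
                      omega = 0.72, c1 = 1.49, c2 = 1.49,
                      rho0 = 1, sc = 15L, fc = 5L,
                      max_gen = 100L, stagnation = 20L,
                      refine_every = 1L, inner_iters = 2L,
                      weights = NULL, seed = 1L) {
  pts <- as_points(x)
  n <- nrow(pts); d <- ncol(pts)
  c_ <- as.integer(centers)
  if (c_ < 2L) stop("need at least 2 clusters", call. = FALSE)
  pop <- as.integer(pop)
  if (pop < 2L) stop("population must be at least 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  uniq <- unique(pts)
  if (nrow(uniq) < c_)
    stop("data has fewer than ", c_, " distinct points", call. = FALSE)

  rng <- local_rng(seed)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  span <- max(hi - lo, 1e-8)
  rho_max <- span
  dim_ <- c_ * d

  # particle positions: centre sets drawn from the data points
  P <- matrix(0, pop, dim_)
  for (i in seq_len(pop)) {
    idx <- rng$sample_int(nrow(uniq), min(c_, nrow(uniq)))
    P[i, ] <- as.numeric(uniq[idx, , drop = FALSE])
  }
  V <- matrix(0, pop, dim_)
  fit_of <- function(v) fcm_fitness(pts, matrix(v, c_, d), m, weights)
  fitness <- apply(P, 1, fit_of)
  pbest <- P
  pbest_fit <- fitness
  gi <- which.min(pbest_fit)
  gbest <- pbest[gi, ]
  gbest_fit <- pbest_fit[gi]

  rho <- rho0; succ <- 0L; fail <- 0L
  gbest_trace <- numeric(0)
  rho_trace <- numeric(0)
  since_improve <- 0L
  gen <- 0L

  clamp_pos <- function(v) pmin(pmax(v, rep(lo, each = c_)), rep(hi, each = c_))

  while (gen < max_gen) {
    gen <- gen + 1L

    # Lamarckian FCM refinement
    if (refine_every >= 1L && gen %% refine_every == 0L) {
      for (i in seq_len(pop)) {
        Z <- matrix(P[i, ], c_, d)
        ok <- TRUE
        for (k in seq_len(inner_iters)) {
          U <- fcm_memberships(fcm_distances(pts, Z), m)
          Z2 <- tryCatch(fcm_centers(pts, U, m, weights), error = function(e) NULL)
          if (is.null(Z2)) { ok <- FALSE; break }
          Z <- Z2
        }
        if (ok) {
          f2 <- fcm_fitness(pts, Z, m, weights)
          if (f2 < fitness[i]) {
            P[i, ] <- as.numeric(Z)
            fitness[i] <- f2
          }
        }
      }
    }

    # pbest / gbest bookkeeping
    better <- fitness < pbest_fit
    pbest[better, ] <- P[better, , drop = FALSE]
    pbest_fit[better] <- fitness[better]
    new_gi <- which.min(pbest_fit)
    improved <- pbest_fit[new_gi] < gbest_fit - 1e-12
    if (pbest_fit[new_gi] < gbest_fit) {
      gi <- new_gi
      gbest <- pbest[gi, ]
      gbest_fit <- pbest_fit[gi]
    }
    gbest_trace[gen] <- gbest_fit
    since_improve <- if (improved) 0L else since_improve + 1L

    st <- rho_update(rho, succ, fail, improved, sc = sc, fc = fc,
                     rho_max = rho_max)
    rho <- st$rho; succ <- st$success_count; fail <- st$failure_count
    rho_trace[gen] <- rho

    if (since_improve >= stagnation) break

    # velocity and position updates
    for (i in seq_len(pop)) {
      if (i == gi) {
        V[i, ] <- gcpso_velocity(P[i, ], V[i, ], pbest[i, ], gbest,
                                 omega = omega, rho = rho, is_best = TRUE,
                                 r = rng$runif(dim_))
      } else {
        V[i, ] <- gcpso_velocity(P[i, ], V[i, ], pbest[i, ], gbest,
                                 omega = omega, c1 = c1, c2 = c2,
                                 is_best = FALSE, r = rng$runif(2 * dim_))
      }
      P[i, ] <- clamp_pos(P[i, ] + V[i, ])
    }
    fitness <- apply(P, 1, fit_of)
  }

  Z <- matrix(gbest, c_, d)
  U <- fcm_memberships(fcm_distances(pts, Z), m)
  out <- list(centers = Z, U = U, m = m,
              objective = gbest_fit, J_trace = gbest_trace,
              gbest_trace = gbest_trace, rho_trace = rho_trace,
              iterations = gen, generations = gen, converged = since_improve >= stagnation,
              weights = weights, n = n, d = d,
              pop = pop, seed = seed, call = match.call())
  class(out) <- c("gcpso_fcm", "fcm")
  out
}

#' @export
print.gcpso_fcm <- function(x, ...) {
  cat(sprintf("Hybrid GCPSO-FCM fit: %d clusters, m = %g, swarm of %d, %d generation(s)\n",
              nrow(x$centers), x$m, x$pop, x$generations))
  cat(sprintf("  gbest J_m = %.6g%s\n", x$objective,
              if (x$converged) " (stagnation stop)" else ""))
  cat("Centers:\n")
  print(round(x$centers, 4))
  invisible(x)
}

#' @export
plot.gcpso_fcm <- function(x, ...) {
  graphics::plot(seq_along(x$gbest_trace), x$gbest_trace, type = "s",
                 xlab = "generation", ylab = expression(J[m]),
                 main = "GCPSO-FCM global-best fitness", ...)
  invisible(x)
}
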