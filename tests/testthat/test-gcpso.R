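test_that("velocity updates follow the GCPSO and canonical PSO rules", {
  # best particle sitting at gbest with zero velocity and rho = 0 is a fixed
  # point (rho_min floor keeps rho positive, so use rho ~ 0)
  v <- gcpso_velocity(3, 0, 3, 3, omega = 0.9, rho = 1e-12, is_best = TRUE,
                      r = 0.5)
  expect_equal(v, 0, tolerance = 1e-10)
  # hand evaluation: x=5, gbest=3, omega*v=1, rho=2, r=0.25
  expect_equal(gcpso_velocity(5, 1, 5, 3, omega = 1, rho = 2, is_best = TRUE,
                              r = 0.25), 0)
  # canonical rule for a non-best particle
  v2 <- gcpso_velocity(1, 2, 4, 6, omega = 0.5, c1 = 2, c2 = 1,
                       is_best = FALSE, r = c(0.5, 0.5))
  expect_equal(v2, 0.5 * 2 + 2 * 0.5 * (4 - 1) + 1 * 0.5 * (6 - 1))
})

test_that("best-particle positions sample uniformly around gbest + omega v", {
  set.seed(99)
  gbest <- 2; omega_v <- 0.6; rho <- 1.5
  n <- 20000
  r <- runif(n)
  pos <- gbest + omega_v + rho * (1 - 2 * r)  # x + v' with the GCPSO rule
  centre <- gbest + omega_v
  se <- rho / sqrt(3) / sqrt(n)
  expect_lt(abs(mean(pos) - centre), 3 * se)
  expect_true(all(pos >= centre - rho & pos <= centre + rho))
  # the same positions arise through gcpso_velocity
  pos2 <- 5 + gcpso_velocity(rep(5, n), rep(omega_v, n), rep(5, n),
                             rep(gbest, n), omega = 1,
                             rho = rho, is_best = TRUE, r = r)
  expect_equal(sort(pos2), sort(pos), tolerance = 1e-12)
})

test_that("search radius doubles after 16 straight successes, halves after 6 failures", {
  s <- list(rho = 1, success_count = 0L, failure_count = 0L)
  for (i in 1:15) s <- rho_update(s$rho, s$success_count, s$failure_count, TRUE)
  expect_equal(s$rho, 1)   # threshold not yet exceeded
  s <- rho_update(s$rho, s$success_count, s$failure_count, TRUE)
  expect_equal(s$rho, 2)
  expect_equal(s$success_count, 0L)

  f <- list(rho = 1, success_count = 0L, failure_count = 0L)
  for (i in 1:5) f <- rho_update(f$rho, f$success_count, f$failure_count, FALSE)
  expect_equal(f$rho, 1)
  f <- rho_update(f$rho, f$success_count, f$failure_count, FALSE)
  expect_equal(f$rho, 0.5)

  # alternating success/failure never moves rho
  a <- list(rho = 1, success_count = 0L, failure_count = 0L)
  for (i in 1:40) a <- rho_update(a$rho, a$success_count, a$failure_count, i %% 2 == 0)
  expect_equal(a$rho, 1)
  # a success wipes the failure streak and vice versa
  b <- rho_update(1, 0L, 4L, TRUE)
  expect_equal(b$failure_count, 0L)
  expect_equal(b$success_count, 1L)
})

test_that("radius stays within its clamp bounds", {
  s <- list(rho = 1e-9, success_count = 0L, failure_count = 5L)
  s <- rho_update(s$rho, s$success_count, s$failure_count, FALSE)
  expect_gte(s$rho, 1e-10)
  s2 <- rho_update(3, 15L, 0L, TRUE, rho_max = 4)
  expect_lte(s2$rho, 4)
})

test_that("hybrid optimiser is elitist with a monotone global best", {
  set.seed(17)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  fit <- gcpso_fcm(x, centers = 2, max_gen = 30, seed = 17)
  expect_true(all(diff(fit$gbest_trace) <= 1e-12))
  expect_true(all(abs(rowSums(fit$U) - 1) < 1e-9))
  # final gbest no worse than any single particle evaluated anywhere
  expect_lte(fit$objective, fit$gbest_trace[1])
  expect_error(gcpso_fcm(x, centers = 2, pop = 1), "at least 2")
})

test_that("hybrid runs are reproducible under a fixed seed", {
  set.seed(2)
  x <- matrix(rnorm(80), 40, 2)
  f1 <- gcpso_fcm(x, centers = 2, max_gen = 15, seed = 5)
  f2 <- gcpso_fcm(x, centers = 2, max_gen = 15, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$gbest_trace, f2$gbest_trace)
})

test_that("hybrid matches or beats plain FCM on a multimodal fixture", {
  # three tight blobs plus a small fourth: with c = 4 there are two
  # competing layouts (split a big blob vs dedicate a centre to the small
  # one), so plain FCM's outcome depends on its start
  wins <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    x <- rbind(cbind(rnorm(40, 0, .3), rnorm(40, 0, .3)),
               cbind(rnorm(40, 10, .3), rnorm(40, 0, .3)),
               cbind(rnorm(40, 0, .3), rnorm(40, 10, .3)),
               cbind(rnorm(10, 10, .3), rnorm(10, 10, .3)))
    fh <- gcpso_fcm(x, centers = 4, seed = s)
    ff <- fcm(x, centers = 4, seed = s)
    wins <- wins + (fh$objective <= ff$objective + 1e-9)
  }
  expect_gte(wins, 14)  # at least 70% of trials
})

test_that("hybrid recovers the centres of three separated Gaussian blobs", {
  true_means <- rbind(c(0, 0), c(8, 0), c(4, 7))
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    x <- do.call(rbind, lapply(1:3, function(k)
      cbind(rnorm(50, true_means[k, 1]), rnorm(50, true_means[k, 2]))))
    Z <- coef(gcpso_fcm(x, centers = 3, seed = s))
    err <- sapply(1:3, function(k)
      min(sqrt(rowSums((Z - matrix(true_means[k, ], 3, 2, byrow = TRUE))^2))))
    hits <- hits + all(err < 0.5)
  }
  expect_gte(hits, 4)
})
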