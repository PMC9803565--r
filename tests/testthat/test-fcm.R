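test_that("distance matrix follows the Euclidean definition", {
  D <- fcm_distances(c(0, 4), c(0, 3))
  expect_equal(D, matrix(c(0, 4, 3, 1), 2, 2))
  # translation invariance and dimension checks
  x <- matrix(rnorm(20), 10, 2); z <- matrix(rnorm(6), 3, 2)
  expect_equal(fcm_distances(x + 5, z + 5), fcm_distances(x, z),
               tolerance = 1e-9)
  expect_error(fcm_distances(x, matrix(0, 2, 3)), "dimension")
})

test_that("membership update matches the closed form and its conventions", {
  U <- fcm_memberships(matrix(c(1, 2), 1), m = 2)
  expect_equal(as.numeric(U), c(0.8, 0.2))
  # zero distance: all membership to the coincident centre
  U0 <- fcm_memberships(matrix(c(0, 3), 1), m = 2)
  expect_equal(as.numeric(U0), c(1, 0))
  # equidistant: symmetric split for any fuzzifier
  for (m in c(1.3, 2, 4))
    expect_equal(as.numeric(fcm_memberships(matrix(c(2, 2), 1), m)), c(0.5, 0.5))
  # ties among several zero distances split equally
  Uz <- fcm_memberships(matrix(c(0, 0, 5), 1), m = 2)
  expect_equal(as.numeric(Uz), c(0.5, 0.5, 0))
  expect_error(fcm_memberships(matrix(1, 1, 2), m = 1), "m must be > 1")
})

test_that("centre update is the membership-weighted mean", {
  U <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  Z <- fcm_centers(c(0, 10), U, m = 2)
  expect_equal(as.numeric(Z), c(0.4 / 0.68, 6.4 / 0.68), tolerance = 1e-12)
  # crisp memberships reduce to class means, any m
  Uc <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(as.numeric(fcm_centers(c(1, 3, 10), Uc, m = 3)), c(2, 10))
  # centres stay inside the data's convex hull
  set.seed(4)
  x <- matrix(runif(40), 20, 2)
  U2 <- matrix(runif(40), 20, 2); U2 <- U2 / rowSums(U2)
  Z2 <- fcm_centers(x, U2, m = 2)
  expect_true(all(Z2 >= min(x) & Z2 <= max(x)))
})

test_that("objective matches hand evaluation and is non-negative", {
  U <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  J <- fcm_objective(c(0, 10), U, c(0, 10), m = 2)
  expect_equal(J, 8)
  expect_equal(fcm_objective(c(0, 10), rbind(c(1, 0), c(0, 1)), c(0, 10), 2), 0)
})

test_that("alternating optimisation descends and keeps row sums at one", {
  set.seed(12)
  for (trial in 1:20) {
    x <- matrix(rnorm(60, mean = sample(c(0, 6), 30, TRUE)), 30, 2)
    fit <- fcm(x, centers = 3, seed = trial, max_iter = 40)
    expect_true(all(diff(fit$J_trace) <= 1e-8))
    expect_true(all(abs(rowSums(fit$U) - 1) < 1e-9))
    expect_gte(fit$objective, 0)
  }
})

test_that("well-separated 1-D blobs are recovered to within 2 units", {
  set.seed(5)
  x <- c(rnorm(100, 10, 2), rnorm(100, 200, 2))
  fit <- fcm(x, centers = 2, seed = 3)
  expect_equal(sort(coef(fit)[, 1]), c(10, 200), tolerance = 2 / 10)
})

test_that("point order only permutes the recovered clusters", {
  set.seed(8)
  x <- c(rnorm(40, 0), rnorm(40, 50))
  f1 <- fcm(x, centers = 2, seed = 2)
  perm <- sample(length(x))
  f2 <- fcm(x[perm], centers = 2, seed = 2)
  expect_equal(sort(coef(f1)[, 1]), sort(coef(f2)[, 1]), tolerance = 1e-3)
  l1 <- fitted(f1)[perm]; l2 <- fitted(f2)
  agree <- max(mean(l1 == l2), mean(l1 != l2))  # up to label swap
  expect_equal(agree, 1)
})

test_that("near-crisp fuzzy fit agrees with exhaustive best 2-partition", {
  set.seed(21)
  for (trial in 1:5) {
    x <- round(runif(8, 0, 100))
    if (length(unique(x)) < 3) next
    g_opt <- oracle_best_2partition(x)
    fits <- lapply(1:5, function(s)
      fcm(x, centers = 2, m = 1.05, seed = s, max_iter = 200))
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
    g_fit <- fitted(fit) == 1
    expect_true(all(g_fit == g_opt) || all(g_fit == !g_opt))
  }
})

test_that("fit agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  set.seed(33)
  x <- matrix(c(rnorm(60, 0), rnorm(60, 12)), ncol = 2)
  ours <- fcm(x, centers = 2, seed = 1, tol = 1e-9, max_iter = 300)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 300)
  o1 <- coef(ours)[order(coef(ours)[, 1]), ]
  o2 <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(o1), unname(o2), tolerance = 1e-3)
})

test_that("degenerate and invalid inputs are rejected with diagnostics", {
  expect_error(fcm(rep(5, 10), centers = 2), "distinct")
  expect_error(fcm(1:10, centers = 1), "at least 2")
  expect_error(fcm(1:3, centers = 3), "more points than clusters")
})
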