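test_that("bilateral filter leaves constant images unchanged", {
  flat <- matrix(77, 20, 20)
  for (p in list(bilateral_params(1.8, 1), bilateral_params(5, 100, 5)))
    expect_equal(bilateral_filter(flat, p), flat, tolerance = 1e-12)
})

test_that("bilateral filter matches the brute-force oracle on small images", {
  set.seed(3)
  for (i in 1:20) {
    h <- sample(3:7, 1); w <- sample(3:7, 1)
    img <- matrix(runif(h * w, 0, 255), h, w)
    sd_ <- runif(1, 0.5, 3); sr <- runif(1, 1, 60)
    win <- sample(c(3, 5, 7), 1)
    out <- bilateral_filter(img, bilateral_params(sd_, sr, win))
    expect_lt(max(abs(out - oracle_bilateral(img, sd_, sr, win))), 1e-10)
  }
})

test_that("range scale below an edge preserves it; above an edge smooths it", {
  # step of height 10 across the image centre
  step <- matrix(rep(c(100, 110), each = 16 * 16), 16, 32)
  height_after <- function(sr) {
    out <- bilateral_filter(step, bilateral_params(1.8, sr, 11))
    mean(out[, 17]) - mean(out[, 16])
  }
  expect_gte(height_after(2), 9)    # sigma_r << step: filter cannot touch it
  expect_lte(height_after(50), 5)   # sigma_r >> step: discontinuity removed
})

test_that("per-pixel parameter maps are honoured", {
  set.seed(9)
  img <- matrix(runif(100, 0, 255), 10, 10)
  sr_map <- matrix(20, 10, 10)
  same <- bilateral_filter(img, bilateral_params(2, 20, 5))
  mapd <- bilateral_filter(img, bilateral_params(2, sr_map, 5))
  expect_equal(mapd, same, tolerance = 1e-12)
  expect_error(bilateral_filter(img, bilateral_params(2, matrix(1, 3, 3), 5)),
               "match image dimensions")
})

test_that("parameter validation rejects bad windows and scales", {
  expect_error(bilateral_params(window = 4), "odd")
  expect_error(bilateral_params(sigma_d = 0), "positive")
  expect_error(bilateral_params(sigma_r = -1), "positive")
})

test_that("block-boundary probe reports step heights and ignores ramps", {
  flat <- matrix(50, 24, 24)
  d0 <- detect_block_discontinuity(flat, 8)
  expect_true(all(d0$vertical == 0) && all(d0$horizontal == 0))

  # jump of 10 exactly at the first vertical block boundary (after col 8)
  img <- matrix(100, 24, 24); img[, 9:24] <- 110
  d1 <- detect_block_discontinuity(img, 8)
  expect_equal(unname(d1$vertical[, 1]), rep(10, 24))
  expect_true(all(d1$vertical[, 2] == 0))

  # smooth ramp: boundary response equals the interior response of the probe
  ramp <- matrix(rep(1:24, each = 24), 24, 24)  # column j has value j
  d2 <- detect_block_discontinuity(ramp, 8)
  interior <- abs(ramp[1, 6] - ramp[1, 4]) / 2 + abs(ramp[1, 7] - ramp[1, 5]) / 2
  expect_equal(unname(d2$vertical[1, 1]), interior)
})

test_that("texture activity is a shifted-invariant local sd", {
  flat <- matrix(12, 16, 16)
  expect_true(all(texture_activity(flat, 5) == 0))

  checker <- outer(1:20, 1:20, function(i, j) ((i + j) %% 2) * 255)
  act <- texture_activity(checker, 3)
  inner <- act[5:16, 5:16]
  expect_true(all(abs(inner - 127.5) < 1.5))

  img <- matrix(runif(64, 0, 100), 8, 8)
  expect_equal(texture_activity(img + 50, 3), texture_activity(img, 3),
               tolerance = 1e-9)
})

test_that("parameter adaptation follows the discontinuity and texture signals", {
  flat <- matrix(80, 24, 24)
  base <- bilateral_params(sigma_d = 1.8, sigma_r = 4, window = 11)
  p0 <- adapt_params(detect_block_discontinuity(flat, 8),
                     texture_activity(flat, 7), base, noise_sigma = 4)
  expect_true(all(p0$sigma_r == 4))
  expect_true(all(p0$sigma_d == 1.8))

  # boundary step of 10 with base sigma_r 4: local sigma_r must reach the step
  img <- matrix(100, 24, 24); img[, 9:24] <- 110
  p1 <- adapt_params(detect_block_discontinuity(img, 8),
                     texture_activity(flat, 7), base, noise_sigma = 4)
  expect_true(all(p1$sigma_r[, 8] >= 10))
  expect_true(all(p1$sigma_r[, 9] >= 10))
  expect_true(all(p1$sigma_r[, 16] == 4))  # quiet boundary stays at base

  # higher texture activity gives smaller (or equal) sigma_d
  tex <- matrix(0, 24, 24); tex[, 13:24] <- 30
  p2 <- adapt_params(detect_block_discontinuity(flat, 8), tex, base,
                     noise_sigma = 5)
  expect_true(all(p2$sigma_d[, 1:12] >= p2$sigma_d[, 13:24]))
  expect_true(all(p2$sigma_d >= 0.3 * 1.8 - 1e-12))
})
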