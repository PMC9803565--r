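test_that("kernel evaluations match their closed forms", {
  x <- c(1, 2); y <- c(3, 4)
  expect_equal(kernel_eval(kernel_spec("linear"), x, y), 11)
  expect_equal(kernel_eval(kernel_spec("polynomial", degree = 1), x, y), 12)
  expect_equal(kernel_eval(kernel_spec("polynomial", degree = 3), x, y), 12^3)
  # radial families: unit self-similarity for any point and scale
  for (s in c(0.5, 1, 5)) {
    expect_equal(kernel_eval(kernel_spec("grbf", sigma = s), x, x), 1)
    expect_equal(kernel_eval(kernel_spec("erbf", sigma = s), x, x), 1)
  }
  # ||x - y|| = sigma gives exp(-1/2) for the Gaussian
  expect_equal(kernel_eval(kernel_spec("grbf", sigma = 2), c(0, 0), c(2, 0)),
               exp(-0.5))
  expect_equal(kernel_eval(kernel_spec("erbf", sigma = 2), c(0, 0), c(3, 0)),
               exp(-3 / 8))
  expect_equal(kernel_eval(kernel_spec("anova", degree = 2, sigma = 1),
                           c(0, 0), c(1, 0)),
               (exp(-1) + 1)^2)
  expect_error(kernel_eval(kernel_spec("linear"), 1:2, 1:3), "dimension")
})

test_that("kernel matrices agree with pairwise evaluation and are PSD", {
  set.seed(20)
  X <- matrix(rnorm(40), 10, 4)
  for (fam in c("linear", "polynomial", "grbf", "erbf", "anova")) {
    sp <- kernel_spec(fam, degree = 2, sigma = 1.5)
    K <- kernel_matrix(sp, X)
    K0 <- outer(1:10, 1:10, Vectorize(function(i, j)
      kernel_eval(sp, X[i, ], X[j, ])))
    expect_equal(K, K0, tolerance = 1e-10)
    expect_equal(K, t(K), tolerance = 1e-12)
    if (fam %in% c("linear", "polynomial", "grbf", "erbf"))
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
  }
})

test_that("separable toy problems are fit perfectly", {
  # linearly separable 4-point set
  x <- rbind(c(0, 0), c(0, 1), c(3, 3), c(4, 3))
  y <- c(FALSE, FALSE, TRUE, TRUE)
  fit <- kernel_svm(x, y, kernel_spec("linear"), C = 10)
  expect_equal(predict(fit, x) > 0, y)

  # XOR under a Gaussian kernel
  xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yy <- c(1, 1, -1, -1)
  fx <- kernel_svm(xx, yy, kernel_spec("grbf", sigma = 1), C = 10)
  expect_equal(unname(predict(fx, xx)), yy)

  # decision values are sign-consistent with labels on the training set
  f <- predict(fx, xx, type = "decision")
  expect_true(all(sign(f) == yy))
  expect_error(kernel_svm(xx, rep(1, 4), kernel_spec("linear")),
               "both classes")
})

test_that("classifier scores follow the confusion-count definitions", {
  y <- c(1, 1, -1, -1)
  pred <- c(1, -1, -1, 1)
  out <- evaluate_classifier(NULL, NULL, y, pred = pred)
  expect_equal(unname(out), c(50, 50, 50))
  perfect <- evaluate_classifier(NULL, NULL, y, pred = y)
  expect_equal(unname(perfect), c(100, 100, 100))
  # accuracy is the prevalence-weighted mean of the class rates
  y2 <- c(1, 1, 1, -1)
  p2 <- c(1, -1, 1, -1)
  sc <- evaluate_classifier(NULL, NULL, y2, pred = p2)
  expect_equal(unname(sc["accuracy"]),
               unname(0.75 * sc["sensitivity"] + 0.25 * sc["specificity"]))
})

test_that("tumour vs non-tumour phantom textures are separable by the Gaussian kernel", {
  # two texture classes from the phantom generator: with and without lesion
  n_per <- 15
  feats <- list(); labs <- logical(0)
  for (s in seq_len(n_per)) {
    ph <- make_phantom(phantom_spec(48, 48, tumour_radius = 8, seed = s))
    img1 <- add_noise(ph$image, 8, seed = s)
    img0 <- add_noise(ph$image * (!ph$mask) + 120 * ph$mask, 8, seed = s + 500)
    feats[[2 * s - 1]] <- glcm_feature_vector(img1)
    feats[[2 * s]] <- glcm_feature_vector(img0)
    labs <- c(labs, TRUE, FALSE)
  }
  X <- do.call(rbind, feats)
  res <- svm_cv(X, labs, kernel_spec("grbf", sigma = 3), C = 1, folds = 5,
                seed = 1)
  expect_gte(unname(res["accuracy"]), 90)
})
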