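test_that("l2_normalize maps rows onto the unit hypersphere", {
  expect_equal(as.numeric(l2_normalize(c(3, 4))), c(0.6, 0.8))
  v <- matrix(rnorm(40), 8, 5)
  Vn <- l2_normalize(v)
  expect_lt(max(abs(sqrt(rowSums(Vn^2)) - 1)), 1e-12)
  expect_equal(l2_normalize(Vn), Vn, tolerance = 1e-12)           # idempotent
  expect_equal(l2_normalize(7.3 * v), Vn, tolerance = 1e-12)      # scale invariant
  v[3, ] <- 0
  expect_error(l2_normalize(v), "index 3")
})

test_that("inner-product cosine matches the general cosine on random pairs", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  set.seed(12)
  for (k in 1:100) {
    f <- rnorm(6); g <- rnorm(6)
    expect_equal(cosine_similarity(as.numeric(l2_normalize(f)),
                                   as.numeric(l2_normalize(g))),
                 pairwise_similarity(f, g), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(c(2, 0), c(1, 0)), "unit-norm")
})

test_that("class probabilities sharpen as alpha decreases", {
  T_ <- l2_normalize(matrix(rnorm(15), 3, 5))
  f <- rnorm(5)
  p_eq <- class_probabilities(c(1, 0, 0, 0, 0),
                              matrix(c(0, 1, 0, 0, 0,
                                       0, 0, 1, 0, 0,
                                       0, 0, 0, 1, 0), 3, byrow = TRUE),
                              scale_state(0.7))
  expect_equal(p_eq, rep(1 / 3, 3), tolerance = 1e-12)   # equal cosines
  p9 <- class_probabilities(f, T_, scale_state(0.9))
  p5 <- class_probabilities(f, T_, scale_state(0.5))
  expect_equal(sum(p9), 1, tolerance = 1e-12)
  expect_equal(sum(p5), 1, tolerance = 1e-12)
  expect_gt(max(p5), max(p9))                            # softmax sharpening
})

test_that("feature scaling multiplies unit rows by 1/alpha", {
  Vn <- l2_normalize(matrix(rnorm(20), 4, 5))
  expect_identical(scale_features(Vn, scale_state(1)), Vn)
  expect_equal(sqrt(rowSums(scale_features(Vn, scale_state(0.5))^2)),
               rep(2, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(scale_features(Vn, scale_state(0.9))^2)),
               rep(1 / 0.9, 4), tolerance = 1e-12)
  expect_error(scale_state(0), "alpha")
  expect_error(scale_state(1.2), "alpha")
})

test_that("scale updates follow the clamped gradient rule", {
  s <- scale_state(0.8, eta = 0.1)
  expect_equal(update_scale(s, 0)$alpha, 0.8)
  expect_equal(update_scale(scale_state(1, eta = 0.1), 0.5)$alpha, 0.95)
  expect_equal(update_scale(s, 1e6)$alpha, 1e-3)   # clamped at epsilon
  expect_equal(update_scale(s, -1e6)$alpha, 1)     # clamped at 1
  s2 <- update_scale(s, 0.3)
  expect_equal(s2$eta, s$eta)
  expect_true(s2$learnable)
  expect_error(update_scale(s, NaN), "non-finite")
  expect_error(update_scale(scale_state(0.5, learnable = FALSE), 0.1),
               "not learnable")
})

test_that("analytic dL/dalpha matches finite differences", {
  set.seed(13)
  for (k in 1:5) {
    f <- rnorm(6)
    T_ <- matrix(rnorm(24), 4, 6)
    y <- sample(4, 1)
    a0 <- runif(1, 0.2, 0.95)
    g <- class_prob_alpha_grad(f, T_, y, scale_state(a0))
    ce <- function(a) {
      -log(class_probabilities(f, T_, scale_state(a))[y])
    }
    g_num <- (ce(a0 + 1e-5) - ce(a0 - 1e-5)) / 2e-5
    expect_lt(abs(g - g_num) / max(abs(g_num), 1e-8), 1e-4)
  }
})
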