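test_that("pairwise similarity is the normalized dot product", {
  expect_equal(pairwise_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(pairwise_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(pairwise_similarity(c(3, 4), c(4, 3)), 24 / 25)
  # symmetric and scale-invariant
  f <- rnorm(6); g <- rnorm(6)
  expect_equal(pairwise_similarity(f, g), pairwise_similarity(g, f))
  expect_equal(pairwise_similarity(3.7 * f, g), pairwise_similarity(f, g))
  expect_error(pairwise_similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(pairwise_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("match probabilities are a stable temperature softmax", {
  expect_equal(match_probability(c(0.4, 0.4, 0.4), 0.5), rep(1 / 3, 3))
  p <- match_probability(rnorm(7), 0.2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # direct evaluation at tau = 0.1
  expect_equal(match_probability(c(1, 0), 0.1),
               c(1 / (1 + exp(-10)), exp(-10) / (1 + exp(-10))))
  # stability under large similarities (max subtraction)
  expect_false(any(is.nan(match_probability(c(500, 499), 0.1))))
  # monotone in own similarity
  p1 <- match_probability(c(0.5, 0.2, 0.1), 0.3)
  p2 <- match_probability(c(0.6, 0.2, 0.1), 0.3)
  expect_gt(p2[1], p1[1])
  expect_error(match_probability(c(1, 0), 1.5), "tau")
})

test_that("contrastive loss matches hand-derived values and invariances", {
  expect_equal(contrastive_loss(matrix(1), tau = 0.5), 0)
  # 2x2 identity at tau = 1: 4 * -log(e / (e + 1)) / 2
  expect_equal(contrastive_loss(diag(2), tau = 1), 2 * log(1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(contrastive_loss(diag(2), tau = 1), 0.62652, tolerance = 1e-5)
  S <- matrix(rnorm(25), 5, 5)
  # adding a constant leaves the softmax-based loss unchanged
  expect_equal(contrastive_loss(S + 3.21, 0.3), contrastive_loss(S, 0.3))
  # permutation equivariance: same permutation of rows and columns
  p <- sample(5)
  expect_equal(contrastive_loss(S[p, p], 0.3), contrastive_loss(S, 0.3))
  expect_gte(contrastive_loss(S, 0.3), 0)
  expect_error(contrastive_loss(matrix(0, 2, 3)), "square")
})

test_that("distillation loss is the sum of squared differences", {
  expect_equal(distillation_loss(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(distillation_loss(0.5, 0.3), 0.04)
  a <- rnorm(4); b <- rnorm(4); c_ <- rnorm(3); d <- rnorm(3)
  expect_equal(distillation_loss(c(a, c_), c(b, d)),
               distillation_loss(a, b) + distillation_loss(c_, d))
  expect_error(distillation_loss(1:3, 1:2), "equal length")
})

test_that("loss gradients match central finite differences", {
  set.seed(31)
  S <- matrix(rnorm(16), 4, 4)
  g <- contrastive_loss_grad(S, 0.3)
  g_num <- num_grad(function(x) contrastive_loss(x, 0.3), S)
  expect_lt(rel_err(g, g_num), 1e-4)

  st <- rnorm(5); ss <- rnorm(5)
  g2 <- distillation_loss_grad(st, ss)
  g2_num <- num_grad(function(x) distillation_loss(st, x), ss)
  expect_lt(rel_err(g2, g2_num), 1e-4)
})

test_that("pretraining reduces the contrastive loss and respects lr = 0", {
  corp <- study_corpus()
  scenes <- corp$splits$train[1:20]
  kb <- corp$kb
  # zero learning rate: parameters unchanged, constant loss trace
  fit0 <- pretrain_region_encoder(scenes, kb, teacher = NULL,
                                  alignment_config(lr = 0, epochs = 3, seed = 2))
  ref <- make_region_encoder(wildetect:::descriptor_dim(), 32, seed = 2)
  expect_identical(fit0$encoder$W, ref$W)
  # one epoch, zero step size: a single-row, trivially constant trace
  fit01 <- pretrain_region_encoder(scenes, kb, teacher = NULL,
                                   alignment_config(lr = 0, epochs = 1, seed = 2))
  expect_equal(nrow(fit01$trace), 1)
  expect_identical(fit01$trace$contrastive[1], fit0$trace$contrastive[1])
  # student equal to a frozen teacher: distillation component zero at lr 0
  teacher <- make_region_encoder(wildetect:::descriptor_dim(), 32, seed = 2)
  fit_t <- pretrain_region_encoder(scenes, kb, teacher,
                                   alignment_config(lr = 0, epochs = 2, seed = 2))
  expect_equal(max(fit_t$trace$distillation), 0, tolerance = 1e-12)
  # a real toy run ends lower than it starts
  fit <- pretrain_region_encoder(scenes, kb, teacher = NULL,
                                 alignment_config(epochs = 20, seed = 0))
  expect_lt(mean(tail(fit$trace$contrastive, 3)),
            mean(head(fit$trace$contrastive, 3)))
  # determinism
  fit2 <- pretrain_region_encoder(scenes, kb, teacher = NULL,
                                  alignment_config(epochs = 20, seed = 0))
  expect_identical(fit$encoder$W, fit2$encoder$W)
})

test_that("region descriptors are deterministic and finite", {
  sc <- tiny_scenes()[[1]]
  boxes <- rbind(c(2, 3, 20, 25), c(10.5, 11.2, 40, 60), c(0, 0, 64, 64))
  D <- region_descriptors(sc$image, boxes)
  expect_equal(dim(D), c(3, wildetect:::descriptor_dim()))
  expect_true(all(is.finite(D)))
  expect_identical(D, region_descriptors(sc$image, boxes))
})
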