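test_that("IoU follows intersection over union arithmetic", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)),
               iou(c(5, 0, 15, 10), c(0, 0, 10, 10)))
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("box delta encode/decode round-trips", {
  set.seed(41)
  props <- cbind(runif(20, 0, 30), runif(20, 0, 30), 0, 0)
  props[, 3] <- props[, 1] + runif(20, 5, 25)
  props[, 4] <- props[, 2] + runif(20, 5, 25)
  gts <- props + matrix(rnorm(80, 0, 2), 20, 4)
  gts[, 3] <- pmax(gts[, 3], gts[, 1] + 4)
  gts[, 4] <- pmax(gts[, 4], gts[, 2] + 4)
  dec <- decode_box_deltas(props, encode_box_deltas(props, gts))
  expect_lt(max(abs(dec - gts)), 1e-9)
})

test_that("oracle proposals reproduce ground truth and clip to bounds", {
  sc <- tiny_scenes()[[2]]
  pr <- propose_regions(sc$image, rpn_params("oracle", jitter = 0),
                        gt_boxes = sc$boxes)
  expect_equal(unname(pr$boxes), unname(sc$boxes))
  prj <- propose_regions(sc$image, rpn_params("oracle", jitter = 0.2, seed = 1),
                         gt_boxes = sc$boxes)
  expect_true(all(prj$boxes[, 1] >= 0 & prj$boxes[, 3] <= ncol(sc$image)))
  pr2 <- propose_regions(sc$image, rpn_params("oracle", jitter = 0,
                                              max_proposals = 2),
                         gt_boxes = sc$boxes)
  expect_lte(nrow(pr2$boxes), 2)
  expect_error(propose_regions(sc$image, rpn_params("oracle")), "gt_boxes")
})

test_that("classification loss is cross-entropy with batch summation", {
  expect_equal(classification_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(classification_loss(c(0.5, 0.5, 0) + c(0, 0, 0),
                                   c(1, 0, 0)), log(2))
  # strictly decreasing in the true-class probability
  l <- vapply(seq(0.1, 0.9, 0.2), function(pc) {
    classification_loss(c(pc, 1 - pc), c(1, 0))
  }, numeric(1))
  expect_true(all(diff(l) < 0))
  expect_error(classification_loss(c(0.9, 0.4), c(1, 0)), "sum to 1")
})

test_that("regression loss implements both branch rules", {
  expect_equal(regression_loss(c(0, 0, 0, 0)), 0)
  expect_equal(regression_loss(0.5), 0.125)
  expect_equal(regression_loss(2, mode = "literal"), 2)
  expect_equal(regression_loss(2, mode = "continuous"), 1.5)
  expect_equal(regression_loss(c(0.5, 2), mode = "continuous"), 0.125 + 1.5)
  expect_error(regression_loss(c(NA, 1, 1, 1)), "non-finite")
})

test_that("total loss is the exact unweighted sum of its parts", {
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(0.1, 0.2, 0.3), 0.6)
  expect_identical(total_loss(0.1, 0.2, 0.3, weights = c(1, 1, 1)),
                   total_loss(0.1, 0.2, 0.3))
  parts <- c(0.11, 0.47, 0.02)
  expect_identical(total_loss(parts[1], parts[2], parts[3]) - sum(parts), 0)
})

test_that("NMS suppresses same-class overlaps by score", {
  one <- data.frame(xmin = 0, ymin = 0, xmax = 10, ymax = 10,
                    label = 1L, score = 0.8)
  expect_equal(nrow(nms(one, 0.5)), 1)
  two <- rbind(one, one)
  two$score <- c(0.9, 0.8)
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  disjoint <- data.frame(xmin = c(0, 20), ymin = c(0, 20),
                         xmax = c(10, 30), ymax = c(10, 30),
                         label = c(1L, 1L), score = c(0.9, 0.8))
  expect_equal(nrow(nms(disjoint, 0.5)), 2)
  # different classes are never suppressed against each other
  twoclass <- two; twoclass$label <- c(1L, 2L)
  expect_equal(nrow(nms(twoclass, 0.5)), 2)
})

test_that("training with zero learning rate leaves all weights unchanged", {
  corp <- study_corpus()
  m0 <- init_detector(corp$kb, detector_config(iterations = 20, lr = 0, seed = 4))
  m1 <- train_detector(corp$splits$train[1:10], corp$kb,
                       detector_config(iterations = 20, lr = 0, seed = 4))
  expect_identical(m1$enc$W, m0$enc$W)
  expect_identical(m1$W_r, m0$W_r)
  expect_identical(m1$w_obj, m0$w_obj)
  expect_identical(m1$scale$alpha, m0$scale$alpha)
})

test_that("a toy training run reduces the combined loss", {
  corp <- study_corpus()
  m <- train_detector(corp$splits$train[1:30], corp$kb,
                      detector_config(iterations = 300, seed = 0,
                                      log_interval = 25))
  expect_lt(tail(m$trace$total, 1), m$trace$total[1])
  expect_true(all(is.finite(m$trace$total)))
})

test_that("training is seed-deterministic", {
  corp <- study_corpus()
  cfg <- detector_config(iterations = 40, seed = 9)
  m1 <- train_detector(corp$splits$train[1:10], corp$kb, cfg)
  m2 <- train_detector(corp$splits$train[1:10], corp$kb, cfg)
  expect_identical(m1$enc$W, m2$enc$W)
  expect_identical(m1$scale$alpha, m2$scale$alpha)
})

test_that("detection on the same image is deterministic; untrained models refuse", {
  m <- study_model("cecs", 1)
  sc <- study_corpus()$splits$test[[1]]
  d1 <- detect(sc$image, m)
  d2 <- detect(sc$image, m)
  expect_identical(d1, d2)
  m_untrained <- init_detector(study_corpus()$kb, detector_config())
  expect_error(detect(sc$image, m_untrained), "untrained")
})

test_that("checkpoint save/load round-trips detections", {
  m <- study_model("cecs", 1)
  dir <- withr::local_tempdir()
  save_detector(m, dir)
  back <- load_detector(dir)
  sc <- study_corpus()$splits$test[[2]]
  expect_equal(detect(sc$image, back), detect(sc$image, m), tolerance = 1e-12)
  expect_error(load_detector(file.path(dir, "nope")), "no checkpoint")
})
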