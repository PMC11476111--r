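box_df <- function(xmin, ymin, xmax, ymax, label = 1L, score = NULL,
                   image_id = "img1") {
  d <- data.frame(image_id = image_id, label = label,
                  xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (!is.null(score)) d$score <- score
  d$area <- (d$xmax - d$xmin) * (d$ymax - d$ymin)
  d
}

test_that("greedy matching enforces one detection per ground truth", {
  gt <- box_df(0, 0, 10, 10)
  det <- box_df(0, 0, 10, 10, score = 0.9)
  m <- match_detections(det, gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  det2 <- rbind(det, det); det2$score <- c(0.9, 0.8)
  m2 <- match_detections(det2, gt, 0.5)
  expect_equal(c(m2$TP, m2$FP), c(1, 1))   # coincident duplicate is FP

  m3 <- match_detections(det[0, ], rbind(gt, box_df(20, 20, 30, 30)), 0.5)
  expect_equal(m3$FN, 2)
  expect_equal(m3$TP + m3$FP, 0)
})

test_that("precision/recall conventions", {
  expect_equal(unname(precision_recall(1, 0, 0)), c(1, 1))
  expect_equal(unname(precision_recall(0, 0, 0))[1], 1)  # no detections, none wrong
  expect_true(is.na(precision_recall(0, 0, 0)["R"]))
  expect_error(precision_recall(-1, 0, 0), "nonnegative")
})

test_that("average precision equals the staircase sum", {
  # single GT, single TP
  expect_equal(average_precision(pr_curve(TRUE, 1)), 1)
  # flags (TP, FP, TP) with 2 GT: 0.5*1 + 0*0.5 + 0.5*(2/3)
  expect_equal(average_precision(pr_curve(c(TRUE, FALSE, TRUE), 2)),
               0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(average_precision(pr_curve(c(FALSE, FALSE), 2)), 0)
  bad <- structure(list(recall = c(0.5, 0.2), precision = c(1, 1)),
                   class = "pr_curve")
  expect_error(average_precision(bad), "nondecreasing")
  # appending FPs after full recall leaves the literal sum unchanged
  full <- pr_curve(c(TRUE, TRUE), 2)
  padded <- pr_curve(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(average_precision(padded), average_precision(full))
})

test_that("AP agrees with a brute-force rank-enumeration oracle", {
  set.seed(17)
  for (k in 1:100) {
    inst <- random_ap_instance()
    m <- match_detections(inst$det, inst$gt, 0.5)
    expect_equal(average_precision(pr_curve(m$det$tp, nrow(inst$gt))),
                 brute_force_ap(m$det$tp, nrow(inst$gt)),
                 tolerance = 1e-12)
  }
})

test_that("mAP averages per-class AP and is relabeling-invariant", {
  gt <- rbind(box_df(0, 0, 10, 10, label = 1L),
              box_df(20, 20, 30, 30, label = 2L))
  det <- rbind(box_df(0, 0, 10, 10, label = 1L, score = 0.9),
               box_df(40, 40, 50, 50, label = 2L, score = 0.8))
  r <- detection_map(det, gt, 0.5)
  expect_equal(unname(r$per_class), c(1, 0))
  expect_equal(r$mAP, 0.5)
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(0.7), 0.7)
  expect_error(mean_ap(c(NA_real_, NA_real_)), "no classes")
  # permute labels: mAP unchanged
  relab <- function(x) ifelse(x == 1L, 2L, 1L)
  gt2 <- gt; gt2$label <- relab(gt2$label)
  det2 <- det; det2$label <- relab(det2$label)
  expect_equal(detection_map(det2, gt2, 0.5)$mAP, r$mAP)
  # degenerate threshold range equals single-threshold mAP
  expect_equal(map_range(det, gt, thresholds = 0.5), r$mAP)
})

test_that("size bands partition boxes and stratify AP", {
  expect_equal(as.character(wildetect:::size_band(c(399, 1023, 1024, 9215, 9216, 10000))),
               c("small", "small", "medium", "medium", "large", "large"))
  gt <- rbind(box_df(0, 0, 20, 20),           # small (400)
              box_df(30, 30, 70, 70))         # medium (1600)
  det <- rbind(box_df(0, 0, 20, 20, score = 0.9),
               box_df(30, 30, 70, 70, score = 0.8))
  ap <- size_stratified_ap(det, gt)
  expect_equal(unname(ap), c(1, 1, NA))
  gt_small <- box_df(0, 0, 20, 20)
  ap2 <- size_stratified_ap(det[1, ], gt_small)
  expect_equal(unname(ap2), c(1, NA, NA))
  # a 100x100 box is large
  gt_big <- box_df(0, 0, 100, 100)
  ap3 <- size_stratified_ap(box_df(0, 0, 100, 100, score = 0.9), gt_big)
  expect_equal(unname(ap3), c(NA, NA, 1))
})

test_that("detection rates: DR, FPR at image level, and MR = 1 - DR exactly", {
  gt <- rbind(box_df(0, 0, 10, 10), box_df(20, 20, 30, 30))
  det <- rbind(box_df(0, 0, 10, 10, score = 0.9),
               box_df(20, 20, 30, 30, score = 0.8))
  r <- detection_rates(det, gt, image_ids = c("img1", "empty1"))
  expect_equal(unname(r), c(1, 1, 0, 0))
  # a detection on the empty image raises image-level FPR
  det_fp <- rbind(det, box_df(1, 1, 9, 9, score = 0.7, image_id = "empty1"))
  r2 <- detection_rates(det_fp, gt, image_ids = c("img1", "empty1"))
  expect_equal(unname(r2["FPR"]), 1)
  # no detections at all
  r3 <- detection_rates(det[0, ], gt, image_ids = "img1")
  expect_equal(unname(r3["DR"]), 0)
  expect_equal(unname(r3["MR"]), 1)
  # complement identity on a partial case
  det_partial <- det[1, ]
  r4 <- detection_rates(det_partial, gt, image_ids = "img1")
  expect_identical(unname(r4["MR"]), 1 - unname(r4["DR"]))
})

test_that("confusion matrix routes hits, misses and false alarms", {
  gt <- rbind(box_df(0, 0, 10, 10, label = 1L),
              box_df(20, 20, 30, 30, label = 2L))
  det <- rbind(box_df(0, 0, 10, 10, label = 1L, score = 0.9),
               box_df(20, 20, 30, 30, label = 2L, score = 0.8))
  M <- confusion_matrix(det, gt, classes = c(1L, 2L))
  expect_equal(diag(M), c("1" = 1, "2" = 1, background = 0))
  expect_equal(sum(M), 2)
  # one class systematically predicted as the other
  det_swap <- det; det_swap$label <- c(2L, 1L)
  M2 <- confusion_matrix(det_swap, gt, classes = c(1L, 2L), normalize = TRUE)
  expect_equal(M2["1", "2"], 1)
  expect_equal(M2["2", "1"], 1)
  expect_true(all(abs(rowSums(M2[1:2, ]) - 1) < 1e-12))
  # unmatched GT goes to the background column
  M3 <- confusion_matrix(det[0, ], gt, classes = c(1L, 2L))
  expect_equal(unname(M3[1:2, "background"]), c(1, 1))
})

test_that("perfect oracle predictions yield mAP = 1", {
  corp <- study_corpus()
  gt <- scenes_to_gt(corp$splits$test)
  oracle <- gt
  oracle$score <- 1
  r <- detection_map(oracle, gt, 0.5)
  expect_equal(r$mAP, 1)
  expect_equal(map_range(oracle, gt), 1)
})

test_that("absence detection counts silent empty scenes", {
  m <- study_model("cecs", 1)
  empties <- generate_dataset(tiny_catalog(), 10, scene_spec(n_targets = 0),
                              seed = 99)
  rate <- absence_detection(empties, m)
  expect_gte(rate, 0); expect_lte(rate, 1)
  # nothing can fire at an impossible threshold
  expect_equal(absence_detection(empties, m, conf_threshold = 1.01), 1)
  expect_error(absence_detection(tiny_scenes(), m), "no empty scenes")
})

test_that("evaluation reports serialize", {
  m <- study_model("cecs", 1)
  rep <- evaluate_detector(m, study_corpus()$splits$test[1:5])
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "eval_report.json")))
  doc <- jsonlite::read_json(file.path(dir, "eval_report.json"))
  expect_equal(doc$mAP50, rep$mAP50, tolerance = 1e-9)
})
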