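# Detection metric suite: greedy IoU matching, PR curves, AP/mAP over IoU
# thresholds, size-stratified AP, detection/miss rates, confusion matrix,
# and empty-shot absence testing.

#' Convert scenes to a ground-truth table
#'
#' @param scenes List of `annotated_scene` objects.
#' @return Data frame with `image_id`, `label`, box columns and `area`.
#' @export
scenes_to_gt <- function(scenes) {
  rows <- lapply(scenes, function(sc) {
    if (nrow(sc$boxes) == 0) return(NULL)
    data.frame(image_id = sc$scene_id, label = sc$labels,
               xmin = sc$boxes[, 1], ymin = sc$boxes[, 2],
               xmax = sc$boxes[, 3], ymax = sc$boxes[, 4])
  })
  gt <- do.call(rbind, rows)
  if (is.null(gt)) {
    gt <- data.frame(image_id = character(0), label = integer(0),
                     xmin = numeric(0), ymin = numeric(0),
                     xmax = numeric(0), ymax = numeric(0))
  }
  gt$area <- (gt$xmax - gt$xmin) * (gt$ymax - gt$ymin)
  gt
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in descending confidence; each is matched to
#' the unmatched ground-truth box of the same class (same image) with the
#' highest IoU at or above the threshold, otherwise it is a false
#' positive. Ground-truth boxes left unmatched are false negatives; each
#' GT can absorb at most one detection.
#'
#' @param detections Data frame with `image_id`, `label`, `score` and box
#'   columns.
#' @param ground_truth Data frame as from [scenes_to_gt()].
#' @param iou_threshold Match threshold.
#' @param class_agnostic Match across classes (used by the confusion
#'   matrix).
#' @return List with `det` (the detections, sorted, plus `tp` flag and
#'   `gt_index`), counts `TP`, `FP`, `FN`, and the per-GT `gt_matched`
#'   flags.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5,
                             class_agnostic = FALSE) {
  det <- detections[order(detections$score, decreasing = TRUE), , drop = FALSE]
  gt_matched <- rep(FALSE, nrow(ground_truth))
  tp <- logical(nrow(det))
  gt_index <- rep(NA_integer_, nrow(det))
  if (nrow(det) > 0) {
    for (i in seq_len(nrow(det))) {
      cand <- which(!gt_matched &
                      ground_truth$image_id == det$image_id[i] &
                      (class_agnostic | ground_truth$label == det$label[i]))
      if (length(cand) == 0) next
      ious <- vapply(cand, function(j) {
        box_iou_pair(as.numeric(det[i, c("xmin", "ymin", "xmax", "ymax")]),
                     as.numeric(ground_truth[j, c("xmin", "ymin", "xmax", "ymax")]))
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        tp[i] <- TRUE
        gt_index[i] <- cand[best]
        gt_matched[cand[best]] <- TRUE
      }
    }
  }
  det$tp <- tp
  det$gt_index <- gt_index
  list(det = det, TP = sum(tp), FP = sum(!tp), FN = sum(!gt_matched),
       gt_matched = gt_matched)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`. With no detections at
#' all, precision is 1 by convention (none were wrong); recall is `NA`
#' when there is no ground truth.
#'
#' @param TP,FP,FN Nonnegative counts.
#' @return Named vector `c(P, R)`.
#' @export
precision_recall <- function(TP, FP, FN) {
  if (TP < 0 || FP < 0 || FN < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  P <- if (TP + FP == 0) 1 else TP / (TP + FP)
  R <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  c(P = P, R = R)
}

#' Precision-recall curve from ranked match flags
#'
#' @param tp_flags Logical TP flags in descending-confidence order.
#' @param n_gt Number of ground-truth boxes.
#' @return An object of class `pr_curve` with `recall` and `precision` at
#'   every rank.
#' @export
pr_curve <- function(tp_flags, n_gt) {
  stopifnot(n_gt >= 0)
  ctp <- cumsum(tp_flags)
  k <- seq_along(tp_flags)
  structure(list(recall = if (n_gt > 0) ctp / n_gt else rep(0, length(k)),
                 precision = ctp / k, n_gt = n_gt), class = "pr_curve")
}

#' Average precision of a PR curve
#'
#' The default is the literal staircase sum `AP = sum_k (R_k - R_{k-1})
#' P_k` with `R_0 = 0`; `mode = "coco101"` uses the 101-point interpolated
#' area (max precision at recall at or above each of 101 evenly spaced
#' recall levels).
#'
#' @param pr A [pr_curve()].
#' @param mode `"literal"` or `"coco101"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pr, mode = c("literal", "coco101")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pr, "pr_curve"))
  r <- pr$recall; p <- pr$precision
  if (length(r) == 0) return(0)
  if (any(diff(r) < -1e-12)) {
    stop("recall must be nondecreasing", call. = FALSE)
  }
  if (mode == "literal") {
    sum((r - c(0, r[-length(r)])) * p)
  } else {
    grid <- seq(0, 1, by = 0.01)
    vapply(grid, function(g) {
      ok <- r >= g - 1e-12
      if (any(ok)) max(p[ok]) else 0
    }, numeric(1)) |> mean()
  }
}

# AP for one class at one IoU threshold over a full detection/GT table.
class_ap <- function(detections, ground_truth, cls, iou_threshold,
                     mode = "literal") {
  gt_c <- ground_truth[ground_truth$label == cls, , drop = FALSE]
  det_c <- detections[detections$label == cls, , drop = FALSE]
  if (nrow(gt_c) == 0) return(NA_real_)
  if (nrow(det_c) == 0) return(0)
  m <- match_detections(det_c, gt_c, iou_threshold)
  average_precision(pr_curve(m$det$tp, nrow(gt_c)), mode)
}

#' Mean average precision over classes
#'
#' @param per_class_aps Numeric vector of per-class APs (`NA` entries,
#'   classes absent from the ground truth, are dropped).
#' @return The arithmetic mean.
#' @export
mean_ap <- function(per_class_aps) {
  aps <- per_class_aps[!is.na(per_class_aps)]
  if (length(aps) == 0) {
    stop("no classes with ground truth to average over", call. = FALSE)
  }
  mean(aps)
}

#' mAP at one IoU threshold and averaged over a threshold range
#'
#' `detection_map` computes per-class AP and their mean at a single IoU
#' threshold. `map_range` averages the mAP over a set of thresholds
#' (default 0.50 to 0.95 in steps of 0.05).
#'
#' @param detections,ground_truth Detection and GT tables.
#' @param iou_threshold Single threshold for `detection_map`.
#' @param thresholds Threshold vector for `map_range`.
#' @param mode AP mode passed to [average_precision()].
#' @return `detection_map`: list with `per_class` and `mAP`;
#'   `map_range`: the scalar averaged mAP.
#' @export
detection_map <- function(detections, ground_truth, iou_threshold = 0.5,
                          mode = "literal") {
  classes <- sort(unique(ground_truth$label))
  if (length(classes) == 0) {
    stop("ground truth contains no classes", call. = FALSE)
  }
  aps <- vapply(classes, function(cl) {
    class_ap(detections, ground_truth, cl, iou_threshold, mode)
  }, numeric(1))
  names(aps) <- classes
  list(per_class = aps, mAP = mean_ap(aps))
}

#' @rdname detection_map
#' @export
map_range <- function(detections, ground_truth,
                      thresholds = seq(0.5, 0.95, by = 0.05),
                      mode = "literal") {
  stopifnot(length(thresholds) >= 1)
  mean(vapply(thresholds, function(th) {
    detection_map(detections, ground_truth, th, mode)$mAP
  }, numeric(1)))
}

# COCO area bands: small < 32^2, medium [32^2, 96^2), large >= 96^2.
size_band <- function(area) {
  cut(area, breaks = c(-Inf, 32^2, 96^2, Inf),
      labels = c("small", "medium", "large"), right = FALSE)
}

#' Size-stratified average precision
#'
#' AP restricted to ground truth (and detections) in the COCO area bands:
#' small `< 32^2`, medium `[32^2, 96^2)`, large `>= 96^2`. Bands with no
#' ground truth return `NA`.
#'
#' @param detections,ground_truth Detection and GT tables.
#' @param iou_threshold Match threshold.
#' @return Named vector `c(AP_s, AP_m, AP_l)`.
#' @export
size_stratified_ap <- function(detections, ground_truth, iou_threshold = 0.5) {
  gt_band <- size_band(ground_truth$area)
  det_area <- (detections$xmax - detections$xmin) *
    (detections$ymax - detections$ymin)
  det_band <- size_band(det_area)
  out <- vapply(c("small", "medium", "large"), function(b) {
    gt_b <- ground_truth[gt_band == b, , drop = FALSE]
    if (nrow(gt_b) == 0) return(NA_real_)
    det_b <- detections[det_band == b, , drop = FALSE]
    detection_map(det_b, gt_b, iou_threshold)$mAP
  }, numeric(1))
  names(out) <- c("AP_s", "AP_m", "AP_l")
  out
}

#' Detection-level rates over a test set
#'
#' Precision `P = TP/(TP+FP)`, detection rate `DR = TP/(TP+FN)`, miss
#' rate `MR = 1 - DR` (exact complement), and an image-level false
#' positive rate using empty images as the negative class: an empty image
#' with any detection counts as a false-positive image, one with none as
#' a true negative. `FPR` is `NA` when no empty images are supplied.
#'
#' @param detections,ground_truth Detection and GT tables.
#' @param image_ids All evaluated image ids, including empty images.
#' @param iou_threshold Match threshold.
#' @return Named vector `c(P, DR, FPR, MR)`.
#' @export
detection_rates <- function(detections, ground_truth, image_ids,
                            iou_threshold = 0.5) {
  m <- match_detections(detections, ground_truth, iou_threshold)
  pr <- precision_recall(m$TP, m$FP, m$FN)
  DR <- if (is.na(pr["R"])) NA_real_ else unname(pr["R"])
  MR <- if (is.na(DR)) NA_real_ else 1 - DR
  empty_ids <- setdiff(image_ids, unique(ground_truth$image_id))
  FPR <- NA_real_
  if (length(empty_ids) > 0) {
    fired <- vapply(empty_ids, function(id) any(detections$image_id == id),
                    logical(1))
    FPR <- sum(fired) / length(empty_ids)
  }
  c(P = unname(pr["P"]), DR = DR, FPR = FPR, MR = MR)
}

#' Per-class confusion matrix with background row/column
#'
#' Detections are matched to ground truth class-agnostically (greedy by
#' confidence, IoU at or above the threshold); matched pairs count in
#' cell (true class, predicted class), unmatched ground truth in (true,
#' background) and unmatched detections in (background, predicted).
#'
#' @param detections,ground_truth Detection and GT tables.
#' @param classes Integer vector of class labels (order of rows/columns).
#' @param iou_threshold Match threshold.
#' @param normalize Row-normalize to per-true-class rates.
#' @return A `(C+1) x (C+1)` matrix.
#' @export
confusion_matrix <- function(detections, ground_truth, classes,
                             iou_threshold = 0.5, normalize = FALSE) {
  C <- length(classes)
  labs <- c(as.character(classes), "background")
  M <- matrix(0, C + 1, C + 1, dimnames = list(true = labs, predicted = labs))
  m <- match_detections(detections, ground_truth, iou_threshold,
                        class_agnostic = TRUE)
  det <- m$det
  for (i in seq_len(nrow(det))) {
    p <- match(det$label[i], classes)
    if (det$tp[i]) {
      t_ <- match(ground_truth$label[det$gt_index[i]], classes)
      M[t_, p] <- M[t_, p] + 1
    } else {
      M[C + 1, p] <- M[C + 1, p] + 1
    }
  }
  for (j in which(!m$gt_matched)) {
    t_ <- match(ground_truth$label[j], classes)
    M[t_, C + 1] <- M[t_, C + 1] + 1
  }
  if (normalize) {
    rs <- rowSums(M)
    M <- M / ifelse(rs == 0, 1, rs)
  }
  M
}

#' Object-absence (empty-shot) detection rate
#'
#' Fraction of empty scenes on which the model fires no detection above
#' the confidence threshold.
#'
#' @param empty_scenes Scenes with zero ground-truth boxes.
#' @param model A trained detector.
#' @param conf_threshold Optional confidence override.
#' @return The absence rate in `[0, 1]`.
#' @export
absence_detection <- function(empty_scenes, model, conf_threshold = NULL) {
  empty_scenes <- Filter(function(s) nrow(s$boxes) == 0, empty_scenes)
  if (length(empty_scenes) == 0) {
    stop("no empty scenes supplied", call. = FALSE)
  }
  flags <- vapply(empty_scenes, function(sc) {
    nrow(detect(sc$image, model, conf_threshold = conf_threshold)) == 0
  }, logical(1))
  mean(flags)
}

#' Evaluate a trained detector on a scene set
#'
#' Runs [detect()] on every scene and assembles the full report:
#' per-class AP (literal and 101-point interpolated), mAP at IoU 0.5,
#' mAP averaged over 0.50-0.95, size-stratified AP, detection rates, the
#' confusion matrix, and the empty-shot absence rate when empty scenes
#' are present.
#'
#' @param model Trained `wildlife_detector`.
#' @param scenes Evaluation scenes (may include empty shots).
#' @param conf_threshold Optional confidence override.
#' @return An object of class `eval_report`.
#' @export
evaluate_detector <- function(model, scenes, conf_threshold = NULL) {
  dets <- lapply(scenes, function(sc) {
    d <- detect(sc$image, model, conf_threshold = conf_threshold)
    if (nrow(d) > 0) d$image_id <- sc$scene_id
    d
  })
  dets <- do.call(rbind, Filter(function(d) nrow(d) > 0, dets))
  if (is.null(dets)) {
    dets <- data.frame(image_id = character(0), label = integer(0),
                       score = numeric(0), xmin = numeric(0),
                       ymin = numeric(0), xmax = numeric(0), ymax = numeric(0))
  }
  gt <- scenes_to_gt(scenes)
  image_ids <- vapply(scenes, function(s) s$scene_id, "")
  has_gt <- nrow(gt) > 0
  per_class <- if (has_gt) detection_map(dets, gt, 0.5)$per_class else NULL
  per_class_coco <- if (has_gt) {
    detection_map(dets, gt, 0.5, mode = "coco101")$per_class
  } else NULL
  n_empty <- sum(vapply(scenes, function(s) nrow(s$boxes) == 0, logical(1)))
  absence <- if (n_empty > 0) {
    empty_ids <- image_ids[vapply(scenes, function(s) nrow(s$boxes) == 0,
                                  logical(1))]
    mean(!empty_ids %in% dets$image_id)
  } else NA_real_
  structure(list(
    per_class_ap = per_class,
    per_class_ap_coco = per_class_coco,
    mAP50 = if (has_gt) mean_ap(per_class) else NA_real_,
    mAP50_95 = if (has_gt) map_range(dets, gt) else NA_real_,
    size_ap = if (has_gt) size_stratified_ap(dets, gt) else
      c(AP_s = NA_real_, AP_m = NA_real_, AP_l = NA_real_),
    rates = if (has_gt) detection_rates(dets, gt, image_ids) else
      c(P = NA_real_, DR = NA_real_, FPR = NA_real_, MR = NA_real_),
    confusion = if (has_gt) confusion_matrix(dets, gt, model$classes) else NULL,
    absence_rate = absence,
    n_images = length(scenes), n_empty = n_empty,
    n_detections = nrow(dets),
    detections = dets, ground_truth = gt), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d image(s), %d detection(s)>\n",
              x$n_images, x$n_detections))
  cat(sprintf("  mAP@0.5 = %.3f   mAP@0.5:0.95 = %.3f\n", x$mAP50, x$mAP50_95))
  cat(sprintf("  AP_s/m/l = %.3f / %.3f / %.3f\n",
              x$size_ap[1], x$size_ap[2], x$size_ap[3]))
  cat(sprintf("  P = %.3f  DR = %.3f  FPR = %.3f  MR = %.3f\n",
              x$rates["P"], x$rates["DR"], x$rates["FPR"], x$rates["MR"]))
  if (!is.na(x$absence_rate)) {
    cat(sprintf("  absence rate on %d empty shot(s) = %.3f\n",
                x$n_empty, x$absence_rate))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report An `eval_report`.
#' @param dir Output directory; writes `eval_report.json`,
#'   `per_class_ap.csv` and `confusion_matrix.csv`.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- report[c("mAP50", "mAP50_95", "absence_rate", "n_images",
                  "n_empty", "n_detections")]
  out$size_ap <- as.list(report$size_ap)
  out$rates <- as.list(report$rates)
  out$per_class_ap <- as.list(report$per_class_ap)
  out$per_class_ap_coco <- as.list(report$per_class_ap_coco)
  jsonlite::write_json(out, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(report$per_class_ap)) {
    utils::write.csv(data.frame(class = names(report$per_class_ap),
                                ap_literal = unname(report$per_class_ap),
                                ap_coco101 = unname(report$per_class_ap_coco)),
                     file.path(dir, "per_class_ap.csv"), row.names = FALSE)
  }
  if (!is.null(report$confusion)) {
    utils::write.csv(report$confusion,
                     file.path(dir, "confusion_matrix.csv"))
  }
  invisible(dir)
}

#' Plot a precision-recall curve
#'
#' @param pr A [pr_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pr_curve <- function(pr, ...) {
  stopifnot(inherits(pr, "pr_curve"))
  graphics::plot(pr$recall, pr$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "recall", ylab = "precision", ...)
}
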