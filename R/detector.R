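# Two-stage detection: box arithmetic, proposals, ROI heads, losses,
# training loop and end-to-end inference.

#' Intersection over union of two boxes
#'
#' @param box_a,box_b Length-4 numeric `(xmin, ymin, xmax, ymax)` with
#'   positive width and height.
#' @return A scalar in `[0, 1]`.
#' @export
iou <- function(box_a, box_b) {
  if (box_a[3] <= box_a[1] || box_a[4] <= box_a[2] ||
      box_b[3] <= box_b[1] || box_b[4] <= box_b[2]) {
    stop("degenerate box (non-positive width or height)", call. = FALSE)
  }
  box_iou_pair(box_a, box_b)
}

box_iou_pair <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

# n x m IoU matrix between two box sets.
box_iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  iw <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  ih <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- iw * ih
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, "+") - inter)
}

clip_boxes <- function(boxes, W, H) {
  boxes[, 1] <- clamp(boxes[, 1], 0, W - 1e-6)
  boxes[, 2] <- clamp(boxes[, 2], 0, H - 1e-6)
  boxes[, 3] <- clamp(boxes[, 3], boxes[, 1] + 1e-6, W)
  boxes[, 4] <- clamp(boxes[, 4], boxes[, 2] + 1e-6, H)
  boxes
}

#' Encode and decode box regression deltas
#'
#' Standard parameterization against a proposal: `tx = (gx - px) / pw`,
#' `ty = (gy - py) / ph`, `tw = log(gw / pw)`, `th = log(gh / ph)`.
#' Encoding then decoding recovers the target box exactly.
#'
#' @param proposals,gt_boxes `n x 4` box matrices.
#' @param deltas `n x 4` delta matrix for decoding.
#' @return `encode_box_deltas` returns `n x 4` deltas;
#'   `decode_box_deltas` returns `n x 4` boxes.
#' @export
encode_box_deltas <- function(proposals, gt_boxes) {
  pw <- proposals[, 3] - proposals[, 1]; ph <- proposals[, 4] - proposals[, 2]
  px <- proposals[, 1] + pw / 2; py <- proposals[, 2] + ph / 2
  gw <- gt_boxes[, 3] - gt_boxes[, 1]; gh <- gt_boxes[, 4] - gt_boxes[, 2]
  gx <- gt_boxes[, 1] + gw / 2; gy <- gt_boxes[, 2] + gh / 2
  cbind((gx - px) / pw, (gy - py) / ph, log(gw / pw), log(gh / ph))
}

#' @rdname encode_box_deltas
#' @export
decode_box_deltas <- function(proposals, deltas) {
  pw <- proposals[, 3] - proposals[, 1]; ph <- proposals[, 4] - proposals[, 2]
  px <- proposals[, 1] + pw / 2; py <- proposals[, 2] + ph / 2
  gx <- px + deltas[, 1] * pw
  gy <- py + deltas[, 2] * ph
  gw <- pw * exp(clamp(deltas[, 3], -3, 3))
  gh <- ph * exp(clamp(deltas[, 4], -3, 3))
  cbind(gx - gw / 2, gy - gh / 2, gx + gw / 2, gy + gh / 2)
}

# Anchor grid: `scales` square anchors at every stride position.
anchor_grid <- function(W, H, stride = 8, scales = c(12, 24, 40)) {
  cx <- seq(stride / 2, W - stride / 2 + 1e-9, by = stride)
  cy <- seq(stride / 2, H - stride / 2 + 1e-9, by = stride)
  grid <- expand.grid(cx = cx, cy = cy, s = scales)
  boxes <- cbind(grid$cx - grid$s / 2, grid$cy - grid$s / 2,
                 grid$cx + grid$s / 2, grid$cy + grid$s / 2)
  clip_boxes(boxes, W, H)
}

#' Region proposal parameters
#'
#' @param mode `"oracle"` returns ground-truth boxes under a seeded jitter
#'   (for unit-testing downstream stages); `"anchor"` scores a fixed
#'   anchor grid with a trained objectness head.
#' @param jitter Oracle-mode relative jitter (0 reproduces GT exactly).
#' @param seed Oracle-mode jitter seed.
#' @param max_proposals Cap on returned proposals.
#' @param stride,scales Anchor-mode grid geometry.
#' @param obj_threshold Anchor-mode minimum objectness.
#' @return An object of class `rpn_params`.
#' @export
rpn_params <- function(mode = c("oracle", "anchor"), jitter = 0, seed = 0,
                       max_proposals = 50, stride = 8, scales = c(12, 24, 40),
                       obj_threshold = 0.3) {
  structure(list(mode = match.arg(mode), jitter = jitter, seed = seed,
                 max_proposals = max_proposals, stride = stride,
                 scales = scales, obj_threshold = obj_threshold),
            class = "rpn_params")
}

jitter_boxes <- function(boxes, jitter, W, H) {
  if (nrow(boxes) == 0 || jitter == 0) return(boxes)
  w <- boxes[, 3] - boxes[, 1]; h <- boxes[, 4] - boxes[, 2]
  cx <- boxes[, 1] + w / 2 + stats::rnorm(nrow(boxes), 0, jitter) * w
  cy <- boxes[, 2] + h / 2 + stats::rnorm(nrow(boxes), 0, jitter) * h
  w <- pmax(4, w * exp(stats::rnorm(nrow(boxes), 0, jitter)))
  h <- pmax(4, h * exp(stats::rnorm(nrow(boxes), 0, jitter)))
  clip_boxes(cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2), W, H)
}

#' Generate region proposals for one image
#'
#' @param image `H x W x 3` image array.
#' @param rpn An [rpn_params()] object.
#' @param model Trained detector supplying the objectness head
#'   (anchor mode).
#' @param gt_boxes Ground-truth boxes (oracle mode).
#' @return List with `boxes` (clipped, sorted by objectness) and `scores`.
#' @export
propose_regions <- function(image, rpn, model = NULL, gt_boxes = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (rpn$mode == "oracle") {
    if (is.null(gt_boxes)) stop("oracle proposals require gt_boxes", call. = FALSE)
    boxes <- with_seed(rpn$seed, jitter_boxes(gt_boxes, rpn$jitter, W, H))
    scores <- rep(1, nrow(boxes))
  } else {
    if (is.null(model)) stop("anchor proposals require a trained model", call. = FALSE)
    boxes <- anchor_grid(W, H, rpn$stride, rpn$scales)
    X <- region_descriptors(image, boxes)
    scores <- sigmoid(as.numeric(X %*% model$w_obj) + model$b_obj)
    keep <- scores >= rpn$obj_threshold
    boxes <- boxes[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  ord <- order(scores, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), rpn$max_proposals))]
  list(boxes = boxes[ord, , drop = FALSE], scores = scores[ord])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Per-ROI cross-entropy classification loss
#'
#' `-sum_c y_c log p_c`; zero iff the predicted probability of the true
#' class is 1. The batch loss is the sum over ROIs.
#'
#' @param p Probability vector (must sum to 1 within `1e-6`).
#' @param y One-hot vector of the same length.
#' @return A nonnegative scalar.
#' @export
classification_loss <- function(p, y) {
  if (abs(sum(p) - 1) > 1e-6) {
    stop("class probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(length(p) == length(y))
  -sum(y * log(pmax(p, 1e-12)))
}

#' Smooth-L1 box regression loss
#'
#' Sum over the four delta components of a piecewise loss. The default
#' `"continuous"` variant is the standard smooth L1: `d^2/2` for `|d| < 1`
#' and `|d| - 0.5` otherwise. The `"literal"` mode uses `|d|` for
#' `|d| >= 1` exactly as the printed formula states, at the cost of a jump
#' at `|d| = 1`.
#'
#' @param delta Length-4 (or any length) finite numeric vector of
#'   prediction minus target deltas.
#' @param mode `"continuous"` or `"literal"`.
#' @return A nonnegative scalar.
#' @export
regression_loss <- function(delta, mode = c("continuous", "literal")) {
  mode <- match.arg(mode)
  assert_finite(delta, "regression deltas")
  a <- abs(delta)
  small <- a < 1
  if (mode == "continuous") {
    sum(ifelse(small, a^2 / 2, a - 0.5))
  } else {
    sum(ifelse(small, a^2 / 2, a))
  }
}

smooth_l1_grad <- function(delta) {
  # gradient of the continuous variant w.r.t. delta
  ifelse(abs(delta) < 1, delta, sign(delta))
}

#' Combined detection loss
#'
#' `L = L_contrastive + L_cls + L_reg` (optionally weighted; defaults are
#' the plain unweighted sum).
#'
#' @param l_contrastive,l_cls,l_reg Nonnegative finite components.
#' @param weights Length-3 weights.
#' @return The weighted sum.
#' @export
total_loss <- function(l_contrastive, l_cls, l_reg, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3)
  sum(weights * c(l_contrastive, l_cls, l_reg))
}

#' Class-wise non-maximum suppression
#'
#' Greedy suppression by descending score: within each class, a detection
#' is dropped if its IoU with an already kept detection exceeds the
#' threshold.
#'
#' @param detections Data frame with columns `xmin`, `ymin`, `xmax`,
#'   `ymax`, `label`, `score`.
#' @param iou_threshold Suppression threshold.
#' @return The surviving rows, sorted by descending score.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  if (nrow(detections) == 0) return(detections)
  keep_rows <- integer(0)
  for (cl in unique(detections$label)) {
    rows <- which(detections$label == cl)
    rows <- rows[order(detections$score[rows], decreasing = TRUE)]
    boxes <- as.matrix(detections[rows, c("xmin", "ymin", "xmax", "ymax")])
    kept <- integer(0)
    for (i in seq_along(rows)) {
      ok <- TRUE
      for (j in kept) {
        if (box_iou_pair(boxes[i, ], boxes[j, ]) > iou_threshold) {
          ok <- FALSE; break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    keep_rows <- c(keep_rows, rows[kept])
  }
  out <- detections[keep_rows, , drop = FALSE]
  out[order(out$score, decreasing = TRUE), , drop = FALSE]
}

# Detector configuration ---------------------------------------------------

#' Detector training configuration
#'
#' @param variant One of `"baseline"`, `"ce"`, `"cs"`, `"cecs"`: whether
#'   the concept enhancement block and/or the learnable continuous feature
#'   scaling are active. The baseline fixes `alpha = 1` (plain cosine
#'   classifier); CS variants start `alpha` at `alpha_init`.
#' @param iterations SGD iterations.
#' @param lr Learning rate.
#' @param seed Seed for initialization, sampling and jitter.
#' @param d_feat Shared image/text feature dimension.
#' @param d_attn CEM attention dimension.
#' @param tau Contrastive temperature used during detector training.
#' @param use_contrastive Include the region-text contrastive term of the
#'   combined loss during detector training.
#' @param alpha_init,alpha_learnable,alpha_eta Continuous feature scaling
#'   settings (CS variants only).
#' @param smooth_l1_mode `"continuous"` or `"literal"` regression loss.
#' @param jitter Relative jitter applied to ground-truth boxes to form
#'   positive proposals.
#' @param neg_per_image Random background proposals sampled per image.
#' @param reg_input Input of the box regression head: the raw region
#'   `"descriptor"` (default; class-agnostic spatial cue), or the literal
#'   `"scaled"` / `"normalized"` semantic feature wirings.
#' @param conf_threshold Inference score threshold.
#' @param nms_iou Inference NMS threshold.
#' @param refine_steps Extra box-refinement passes at inference (the
#'   regression head is re-applied on the decoded boxes).
#' @param obj_threshold Minimum anchor objectness at inference.
#' @param max_proposals Proposal cap at inference.
#' @param anchor_stride,anchor_scales Anchor grid geometry.
#' @param log_interval Iterations between trace rows.
#' @return A validated config list.
#' @export
detector_config <- function(variant = c("cecs", "baseline", "ce", "cs"),
                            iterations = 500, lr = 0.1, seed = 0,
                            d_feat = 32, d_attn = 16, tau = 0.1,
                            use_contrastive = TRUE,
                            alpha_init = 0.9, alpha_learnable = TRUE,
                            alpha_eta = 0.01,
                            smooth_l1_mode = c("continuous", "literal"),
                            jitter = 0.08, neg_per_image = 6,
                            reg_input = c("descriptor", "scaled", "normalized"),
                            conf_threshold = 0.5, nms_iou = 0.5,
                            refine_steps = 1,
                            obj_threshold = 0.3, max_proposals = 100,
                            anchor_stride = 8, anchor_scales = c(12, 24, 40),
                            log_interval = 50) {
  variant <- match.arg(variant)
  smooth_l1_mode <- match.arg(smooth_l1_mode)
  reg_input <- match.arg(reg_input)
  check_tau(tau)
  stopifnot(iterations >= 1, lr >= 0)
  list(variant = variant, iterations = iterations, lr = lr, seed = seed,
       reg_input = reg_input,
       d_feat = d_feat, d_attn = d_attn, tau = tau,
       use_contrastive = isTRUE(use_contrastive),
       alpha_init = alpha_init, alpha_learnable = alpha_learnable,
       alpha_eta = alpha_eta, smooth_l1_mode = smooth_l1_mode,
       jitter = jitter, neg_per_image = neg_per_image,
       conf_threshold = conf_threshold, nms_iou = nms_iou,
       refine_steps = refine_steps,
       obj_threshold = obj_threshold, max_proposals = max_proposals,
       anchor_stride = anchor_stride, anchor_scales = anchor_scales,
       log_interval = log_interval)
}

has_cem <- function(variant) variant %in% c("ce", "cecs")
has_cs <- function(variant) variant %in% c("cs", "cecs")

#' Initialize a detector model
#'
#' @param kb Knowledge base whose encoded text features become the frozen
#'   class prototypes.
#' @param config A [detector_config()].
#' @param encoder Optional pretrained region encoder to warm-start from.
#' @return An untrained `wildlife_detector`.
#' @export
init_detector <- function(kb, config = detector_config(), encoder = NULL) {
  stopifnot(inherits(kb, "knowledge_base"))
  d <- config$d_feat
  if (!is.null(encoder)) {
    stopifnot(encoder$d_out == d)
  } else {
    encoder <- make_region_encoder(descriptor_dim(), d, seed = config$seed)
  }
  Tn <- normalize_rows(kb$T)$Vn
  stopifnot(ncol(Tn) == d)
  cem <- if (has_cem(config$variant)) cem_init(d, config$d_attn, seed = config$seed + 7) else NULL
  scale <- if (has_cs(config$variant)) {
    scale_state(config$alpha_init, config$alpha_eta, config$alpha_learnable)
  } else {
    scale_state(1, config$alpha_eta, FALSE)
  }
  structure(list(
    variant = config$variant,
    classes = kb$species_ids,
    class_names = kb$names,
    Tn = Tn,
    enc = encoder,
    cem = cem,
    scale = scale,
    b_bg = 0,   # learnable scalar background logit (cosine-classifier style)
    W_r = matrix(0, 4, if ((config$reg_input %||% "scaled") == "descriptor")
      descriptor_dim() else d),
    b_r = numeric(4),
    w_obj = numeric(descriptor_dim()),
    b_obj = 0,
    config = config,
    trained = FALSE,
    trace = NULL), class = "wildlife_detector")
}

# Forward pass over a descriptor batch; returns everything the backward
# pass and inference need.
detector_forward <- function(model, X) {
  v <- encode_regions(model$enc, X)
  cem_fwd <- NULL
  out <- v
  if (!is.null(model$cem)) {
    cem_fwd <- cem_forward(v, model$Tn, model$cem)
    out <- cem_fwd$out
  }
  nr <- normalize_rows(out)
  u <- scale_features(nr$Vn, model$scale)
  logits <- cbind(u %*% t(model$Tn), model$b_bg)
  probs <- softmax_rows(logits)
  reg_in <- switch(model$config$reg_input %||% "scaled",
                   scaled = u, normalized = nr$Vn, descriptor = X)
  deltas <- sweep(reg_in %*% t(model$W_r), 2, model$b_r, "+")
  list(v = v, cem_fwd = cem_fwd, out = out, nr = nr, u = u, reg_in = reg_in,
       logits = logits, probs = probs, deltas = deltas)
}

sample_negatives <- function(W, H, gt_boxes, n_neg, max_iou = 0.3) {
  if (n_neg == 0) return(empty_boxes())
  cand <- matrix(0, 0, 4)
  tries <- 0
  while (nrow(cand) < n_neg && tries < 8) {
    k <- n_neg * 2
    s <- stats::runif(k, 8, min(W, H) / 1.6)
    a <- stats::runif(k, 0.75, 1.35)
    w <- s; h <- pmin(s * a, H - 1)
    xm <- stats::runif(k, 0, W - w); ym <- stats::runif(k, 0, H - h)
    b <- cbind(xm, ym, xm + w, ym + h)
    if (nrow(gt_boxes) > 0) {
      mi <- apply(box_iou_matrix(b, gt_boxes), 1, max)
      b <- b[mi < max_iou, , drop = FALSE]
    }
    cand <- rbind(cand, b)
    tries <- tries + 1
  }
  cand[seq_len(min(n_neg, nrow(cand))), , drop = FALSE]
}

#' Train a detector
#'
#' Seeded SGD over the combined loss (contrastive + classification +
#' regression). Each iteration samples one scene, forms positive proposals
#' by jittering its ground-truth boxes and negative proposals by sampling
#' background boxes, and updates the region encoder, concept enhancement
#' block (CE variants), scale factor (CS variants), background prototype,
#' regression head and the anchor objectness head.
#'
#' @param scenes Training scenes.
#' @param kb Knowledge base.
#' @param config A [detector_config()].
#' @param encoder Optional pretrained region encoder (warm start).
#' @param val_scenes Optional validation scenes; when supplied, validation
#'   mAP at IoU 0.5 is recorded at every trace interval.
#' @return A trained `wildlife_detector` with a `trace` data frame of
#'   per-interval loss components, `alpha`, and validation mAP.
#' @export
train_detector <- function(scenes, kb, config = detector_config(),
                           encoder = NULL, val_scenes = NULL) {
  model <- init_detector(kb, config, encoder)
  with_gt <- Filter(function(s) nrow(s$boxes) > 0, scenes)
  if (length(with_gt) == 0) stop("no scenes with ground truth to train on",
                                 call. = FALSE)
  integrals <- lapply(scenes, function(s) image_integrals(s$image))
  names(integrals) <- vapply(scenes, function(s) s$scene_id, "")
  lr <- config$lr
  trace <- NULL
  last_good <- model
  acc <- c(con = 0, cls = 0, reg = 0, n = 0)
  iter_seeds <- derive_seeds(config$seed + 13, config$iterations)
  scene_ids <- vapply(scenes, function(s) s$scene_id, "")
  for (it in seq_len(config$iterations)) {
    step <- with_seed(iter_seeds[it], {
      sc <- scenes[[sample.int(length(scenes), 1)]]
      H <- nrow(sc$image); W <- ncol(sc$image)
      gt <- sc$boxes
      # positives: anchors matched to GT at IoU >= 0.5 (the distribution the
      # ROI heads see at inference) plus jittered GT boxes as guaranteed hits
      anchors <- anchor_grid(W, H, config$anchor_stride, config$anchor_scales)
      pos <- jitter_boxes(gt, config$jitter, W, H)
      pos_gt <- seq_len(nrow(gt))
      if (nrow(gt) > 0) {
        I <- box_iou_matrix(anchors, gt)
        hit <- which(apply(I, 1, max) >= 0.5)
        if (length(hit) > 8) hit <- sample(hit, 8)
        if (length(hit) > 0) {
          pos <- rbind(pos, anchors[hit, , drop = FALSE])
          pos_gt <- c(pos_gt, apply(I[hit, , drop = FALSE], 1, which.max))
        }
      }
      neg <- sample_negatives(W, H, gt, config$neg_per_image)
      list(sc = sc, pos = pos, pos_gt = pos_gt, neg = neg)
    })
    sc <- step$sc
    pos <- step$pos; neg <- step$neg
    n_pos <- nrow(pos); n_neg <- nrow(neg)
    n_all <- n_pos + n_neg
    if (n_all == 0) next
    boxes <- rbind(pos, neg)
    ii <- integrals[[sc$scene_id]]
    X <- region_descriptors(ii, boxes)
    y <- c(match(sc$labels[step$pos_gt], model$classes),
           rep(length(model$classes) + 1L, n_neg))

    fw <- detector_forward(model, X)
    C1 <- length(model$classes) + 1L
    Y <- matrix(0, n_all, C1); Y[cbind(seq_len(n_all), y)] <- 1
    # balanced cross-entropy: foreground and background halves weigh equally
    w_row <- numeric(n_all)
    if (n_pos > 0) w_row[seq_len(n_pos)] <- 0.5 / n_pos
    if (n_neg > 0) w_row[n_pos + seq_len(n_neg)] <- 0.5 / n_neg
    if (n_pos == 0 || n_neg == 0) w_row <- rep(1 / n_all, n_all)
    l_cls <- -sum(w_row * rowSums(Y * log(pmax(fw$probs, 1e-12))))
    dlogits <- (fw$probs - Y) * w_row

    # regression on positives
    l_reg <- 0
    dDeltas <- matrix(0, n_all, 4)
    if (n_pos > 0) {
      targets <- encode_box_deltas(pos, sc$boxes[step$pos_gt, , drop = FALSE])
      diff <- fw$deltas[seq_len(n_pos), , drop = FALSE] - targets
      l_reg <- sum(ifelse(abs(diff) < 1, diff^2 / 2, abs(diff) - 0.5)) / n_pos
      dDeltas[seq_len(n_pos), ] <- smooth_l1_grad(diff) / n_pos
    }

    # contrastive over one positive per distinct class in the batch
    l_con <- 0
    dVn_extra <- matrix(0, n_all, ncol(fw$u))
    if (config$use_contrastive && n_pos > 0) {
      sel <- which(!duplicated(y[seq_len(n_pos)]))
      if (length(sel) >= 1) {
        cls_sel <- y[sel]
        S <- fw$nr$Vn[sel, , drop = FALSE] %*% t(model$Tn[cls_sel, , drop = FALSE])
        l_con <- contrastive_loss(S, config$tau)
        dS <- contrastive_loss_grad(S, config$tau)
        dVn_extra[sel, ] <- dS %*% model$Tn[cls_sel, , drop = FALSE]
      }
    }

    l_total <- total_loss(l_con, l_cls, l_reg)
    if (!is.finite(l_total)) {
      warning(sprintf("training aborted at iteration %d: non-finite loss; returning last good state", it))
      model <- last_good
      model$trace <- trace
      attr(model, "aborted") <- it
      return(model)
    }

    # ---- backward ----
    du <- dlogits[, -C1, drop = FALSE] %*% model$Tn
    db_bg <- sum(dlogits[, C1])
    reg_mode <- config$reg_input %||% "scaled"
    if (n_pos > 0 && reg_mode == "scaled") {
      du <- du + dDeltas %*% model$W_r
    }
    if (n_pos > 0 && reg_mode == "normalized") {
      dVn_extra <- dVn_extra + dDeltas %*% model$W_r
    }
    dW_r <- t(dDeltas) %*% fw$reg_in
    db_r <- colSums(dDeltas)
    alpha <- model$scale$alpha
    dVn <- du / alpha + dVn_extra
    dalpha <- -sum(du * fw$nr$Vn) / alpha^2
    dout <- normalize_rows_backward(dVn, fw$nr$Vn, fw$nr$norms)
    if (!is.null(model$cem)) {
      bk <- cem_backward(dout, fw$cem_fwd, model$cem)
      dv <- bk$dV
      model$cem <- cem_update(model$cem, bk$grads, lr)
    } else {
      dv <- dout
    }
    model$enc$W <- model$enc$W - lr * t(dv) %*% X
    model$enc$b <- model$enc$b - lr * colSums(dv)
    model$b_bg <- model$b_bg - lr * db_bg
    model$W_r <- model$W_r - lr * dW_r
    model$b_r <- model$b_r - lr * db_r
    if (model$scale$learnable && lr > 0) {
      model$scale <- update_scale(model$scale, dalpha)
    }

    # objectness head (class-agnostic, raw descriptors)
    obj_y <- c(rep(1, n_pos), rep(0, n_neg))
    p_obj <- sigmoid(as.numeric(X %*% model$w_obj) + model$b_obj)
    dobj <- (p_obj - obj_y) / n_all
    model$w_obj <- model$w_obj - lr * as.numeric(t(X) %*% dobj)
    model$b_obj <- model$b_obj - lr * sum(dobj)

    acc <- acc + c(l_con, l_cls, l_reg, 1)
    if (it %% config$log_interval == 0 || it == config$iterations) {
      val_map <- NA_real_
      if (!is.null(val_scenes)) {
        m_tmp <- model; m_tmp$trained <- TRUE
        val_map <- tryCatch(
          evaluate_detector(m_tmp, val_scenes)$mAP50, error = function(e) NA_real_)
      }
      trace <- rbind(trace, data.frame(
        iteration = it,
        contrastive = acc["con"] / acc["n"],
        classification = acc["cls"] / acc["n"],
        regression = acc["reg"] / acc["n"],
        total = (acc["con"] + acc["cls"] + acc["reg"]) / acc["n"],
        alpha = model$scale$alpha,
        val_mAP50 = val_map, row.names = NULL))
      acc <- c(con = 0, cls = 0, reg = 0, n = 0)
      last_good <- model
    }
  }
  model$trained <- TRUE
  model$trace <- trace
  model
}

#' Run end-to-end detection on one image
#'
#' Full pipeline: anchor proposals scored by the objectness head, region
#' descriptor extraction, encoding, concept enhancement (CE variants),
#' L2 normalization and 1/alpha scaling, cosine-prototype classification,
#' box delta decoding, score thresholding and class-wise NMS.
#' Deterministic given the model weights and the input image.
#'
#' @param image `H x W x 3` integer image array.
#' @param model A trained `wildlife_detector`.
#' @param conf_threshold Minimum class probability (defaults to the
#'   trained config).
#' @param rpn Optional [rpn_params()] override (e.g. oracle proposals).
#' @param gt_boxes Ground-truth boxes when `rpn` is in oracle mode.
#' @return Data frame of detections: `xmin`, `ymin`, `xmax`, `ymax`,
#'   `label` (species id), `score`.
#' @export
detect <- function(image, model, conf_threshold = NULL, rpn = NULL,
                   gt_boxes = NULL) {
  stopifnot(inherits(model, "wildlife_detector"))
  if (!isTRUE(model$trained)) {
    stop("model is untrained; call train_detector() first", call. = FALSE)
  }
  cfg <- model$config
  conf_threshold <- conf_threshold %||% cfg$conf_threshold
  if (is.null(rpn)) {
    rpn <- rpn_params("anchor", max_proposals = cfg$max_proposals,
                      stride = cfg$anchor_stride, scales = cfg$anchor_scales,
                      obj_threshold = cfg$obj_threshold)
  }
  props <- propose_regions(image, rpn, model = model, gt_boxes = gt_boxes)
  empty <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      label = integer(0), score = numeric(0))
  if (nrow(props$boxes) == 0) return(empty)
  ii <- image_integrals(image)
  # iterative box refinement: each pass re-extracts descriptors on the
  # current boxes and re-applies the regression head, so proposals converge
  # onto the target before scoring and NMS
  boxes <- props$boxes
  refine <- (cfg$refine_steps %||% 1) + 1L
  for (pass in seq_len(refine)) {
    X <- region_descriptors(ii, boxes)
    fw <- detector_forward(model, X)
    boxes <- clip_boxes(decode_box_deltas(boxes, fw$deltas),
                        ncol(image), nrow(image))
  }
  C <- length(model$classes)
  cls_idx <- max.col(fw$probs, ties.method = "first")
  # detection confidence: class probability weighted by proposal objectness
  score <- fw$probs[cbind(seq_len(nrow(fw$probs)), cls_idx)] * props$scores
  keep <- cls_idx <= C & score >= conf_threshold
  if (!any(keep)) return(empty)
  boxes <- boxes[keep, , drop = FALSE]
  det <- data.frame(xmin = boxes[, 1], ymin = boxes[, 2],
                    xmax = boxes[, 3], ymax = boxes[, 4],
                    label = model$classes[cls_idx[keep]],
                    score = score[keep])
  nms(det, cfg$nms_iou)
}

#' @export
print.wildlife_detector <- function(x, ...) {
  cat(sprintf("<wildlife_detector variant=%s classes=%d alpha=%.3f %s>\n",
              x$variant, length(x$classes), x$scale$alpha,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
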