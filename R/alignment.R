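#' Cosine similarity of an image feature and a text feature
#'
#' `s = (f . g) / (||f|| ||g||)`; symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param f,g Numeric vectors of equal, nonzero length and nonzero norm.
#' @return A scalar in `[-1, 1]`.
#' @export
pairwise_similarity <- function(f, g) {
  if (length(f) != length(g)) {
    stop("feature vectors must have the same dimension", call. = FALSE)
  }
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  sum(f * g) / (nf * ng)
}

#' Match probabilities from a similarity row
#'
#' Temperature-scaled softmax `P_j = exp(s_j / tau) / sum_k exp(s_k /
#' tau)`, computed with max subtraction for numerical stability.
#'
#' @param s_row Numeric vector of similarities.
#' @param tau Temperature in `(0, 1)`.
#' @return A probability vector summing to 1.
#' @export
match_probability <- function(s_row, tau) {
  check_tau(tau)
  assert_finite(s_row, "similarities")
  softmax_vec(s_row / tau)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop("temperature tau must lie in (0, 1)", call. = FALSE)
  }
  invisible(tau)
}

#' Symmetric region-text contrastive loss
#'
#' For an `N x N` similarity matrix whose diagonal holds the matched
#' pairs, the loss is the negative mean over pairs of the row-wise and
#' column-wise log softmax probabilities of the diagonal, at temperature
#' `tau`:
#' `L = -(1/N) sum_i [log softmax_row(i, i) + log softmax_col(i, i)]`.
#'
#' @param S_matrix Square similarity matrix (matched pairs on the diagonal).
#' @param tau Temperature in `(0, 1)`, or exactly 1 for the unscaled form.
#' @return A nonnegative scalar; 0 for `N = 1`.
#' @export
contrastive_loss <- function(S_matrix, tau = 0.1) {
  S_matrix <- as.matrix(S_matrix)
  if (nrow(S_matrix) != ncol(S_matrix)) {
    stop(sprintf("similarity matrix must be square, got %dx%d",
                 nrow(S_matrix), ncol(S_matrix)), call. = FALSE)
  }
  if (tau != 1) check_tau(tau)
  n <- nrow(S_matrix)
  Z <- S_matrix / tau
  P_row <- softmax_rows(Z)
  P_col <- t(softmax_rows(t(Z)))
  -(1 / n) * sum(log(diag(P_row)) + log(diag(P_col)))
}

#' @rdname contrastive_loss
#' @return `contrastive_loss_grad` returns the `N x N` gradient
#'   `dL/dS`, matching central finite differences.
#' @export
contrastive_loss_grad <- function(S_matrix, tau = 0.1) {
  S_matrix <- as.matrix(S_matrix)
  stopifnot(nrow(S_matrix) == ncol(S_matrix))
  if (tau != 1) check_tau(tau)
  n <- nrow(S_matrix)
  Z <- S_matrix / tau
  P_row <- softmax_rows(Z)
  P_col <- t(softmax_rows(t(Z)))
  I <- diag(n)
  (P_row - I + P_col - I) / (n * tau)
}

#' Teacher-student distillation loss
#'
#' Sum of squared differences between teacher and student similarity
#' values, zero iff they agree exactly.
#'
#' @param s_teacher,s_student Numeric vectors of equal length.
#' @return A nonnegative scalar.
#' @export
distillation_loss <- function(s_teacher, s_student) {
  if (length(s_teacher) != length(s_student)) {
    stop("teacher and student similarity vectors must have equal length",
         call. = FALSE)
  }
  sum((s_teacher - s_student)^2)
}

#' @rdname distillation_loss
#' @return `distillation_loss_grad` returns `dL/ds_student`.
#' @export
distillation_loss_grad <- function(s_teacher, s_student) {
  stopifnot(length(s_teacher) == length(s_student))
  -2 * (s_teacher - s_student)
}

# Region descriptors ------------------------------------------------------
#
# Fixed (untrainable) low-level description of an image region: 4x4 grid
# of per-cell mean RGB, 4x4 grid of per-cell grayscale standard deviation,
# and the log relative box size. Computed with integral images so that
# hundreds of proposals per image stay cheap.

DESCRIPTOR_GRID <- 4L
descriptor_dim <- function() DESCRIPTOR_GRID^2 * 3L + DESCRIPTOR_GRID^2 + 2L

integral_image <- function(M) {
  I <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  cs <- apply(M, 2, cumsum)       # cumulative down rows
  I[-1, -1] <- t(apply(cs, 1, cumsum))  # then across columns
  I
}

# Precompute per-image integral images (RGB channels + gray + gray^2).
image_integrals <- function(image) {
  img <- image / 255
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  list(
    R = integral_image(img[, , 1]),
    G = integral_image(img[, , 2]),
    B = integral_image(img[, , 3]),
    gray = integral_image(gray),
    gray2 = integral_image(gray^2),
    W = ncol(image), H = nrow(image))
}

rect_sums <- function(I, x0, x1, y0, y1) {
  # x0/x1/y0/y1: integer pixel edges (0-based), vectors over boxes
  I[cbind(y1 + 1L, x1 + 1L)] - I[cbind(y0 + 1L, x1 + 1L)] -
    I[cbind(y1 + 1L, x0 + 1L)] + I[cbind(y0 + 1L, x0 + 1L)]
}

#' Extract fixed region descriptors for a set of boxes
#'
#' @param image An `H x W x 3` integer image array (or the cached result
#'   of the internal integral-image precomputation).
#' @param boxes `n x 4` matrix of `(xmin, ymin, xmax, ymax)` boxes.
#' @return An `n x d` descriptor matrix (`d = ` `descriptor_dim()`).
#' @export
region_descriptors <- function(image, boxes) {
  ii <- if (is.list(image) && !is.null(image$gray)) image else image_integrals(image)
  n <- nrow(boxes)
  g <- DESCRIPTOR_GRID
  if (n == 0) return(matrix(numeric(0), 0, descriptor_dim()))
  W <- ii$W; H <- ii$H
  xm <- clamp(boxes[, 1], 0, W - 1); xM <- clamp(boxes[, 3], xm + 1, W)
  ym <- clamp(boxes[, 2], 0, H - 1); yM <- clamp(boxes[, 4], ym + 1, H)
  # integer cell edges, forced strictly monotone
  xe <- matrix(0L, n, g + 1L); ye <- matrix(0L, n, g + 1L)
  for (k in 0:g) {
    xe[, k + 1L] <- as.integer(round(xm + (xM - xm) * k / g))
    ye[, k + 1L] <- as.integer(round(ym + (yM - ym) * k / g))
  }
  out <- matrix(0, n, descriptor_dim())
  col_idx <- 1L
  for (cy in seq_len(g)) {
    for (cx in seq_len(g)) {
      x0 <- xe[, cx]; x1 <- pmax(xe[, cx + 1L], x0 + 1L)
      y0 <- ye[, cy]; y1 <- pmax(ye[, cy + 1L], y0 + 1L)
      x1 <- pmin(x1, W); x0 <- pmin(x0, x1 - 1L)
      y1 <- pmin(y1, H); y0 <- pmin(y0, y1 - 1L)
      area <- (x1 - x0) * (y1 - y0)
      mR <- rect_sums(ii$R, x0, x1, y0, y1) / area
      mG <- rect_sums(ii$G, x0, x1, y0, y1) / area
      mB <- rect_sums(ii$B, x0, x1, y0, y1) / area
      mg <- rect_sums(ii$gray, x0, x1, y0, y1) / area
      m2 <- rect_sums(ii$gray2, x0, x1, y0, y1) / area
      sdg <- sqrt(pmax(m2 - mg^2, 0))
      base <- (cy - 1L) * g + (cx - 1L)
      out[, base * 3L + 1L] <- mR
      out[, base * 3L + 2L] <- mG
      out[, base * 3L + 3L] <- mB
      out[, g * g * 3L + base + 1L] <- sdg
      col_idx <- col_idx + 1L
    }
  }
  out[, descriptor_dim() - 1L] <- log((xM - xm) / W)
  out[, descriptor_dim()] <- log((yM - ym) / H)
  out
}

# Region encoders ----------------------------------------------------------

#' Linear region encoder
#'
#' The trainable student (and, once frozen, teacher) image-region encoder:
#' a seeded linear map from the fixed region descriptor to the shared
#' image-text feature space.
#'
#' @param d_in Descriptor dimension (default [descriptor_dim()]).
#' @param d_out Feature dimension.
#' @param seed Initialization seed.
#' @return An object of class `region_encoder` with weight `W` and bias `b`.
#' @export
make_region_encoder <- function(d_in = descriptor_dim(), d_out = 32, seed = 0) {
  structure(list(W = rnorm_matrix(d_out, d_in, seed, sd = 1 / sqrt(d_in)),
                 b = numeric(d_out), d_in = d_in, d_out = d_out),
            class = "region_encoder")
}

#' Encode region descriptors into features
#'
#' @param encoder A `region_encoder`.
#' @param X `n x d_in` descriptor matrix.
#' @return `n x d_out` feature matrix `X W' + b`.
#' @export
encode_regions <- function(encoder, X) {
  stopifnot(inherits(encoder, "region_encoder"), ncol(X) == encoder$d_in)
  sweep(X %*% t(encoder$W), 2, encoder$b, "+")
}

# Normalize rows to unit norm and return the backward pass ingredients.
normalize_rows <- function(V) {
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero feature row at index %s; cannot normalize",
                 paste(which(nrm == 0), collapse = ", ")), call. = FALSE)
  }
  list(Vn = V / nrm, norms = nrm)
}

# dL/dV given dL/dVn for row-wise L2 normalization.
normalize_rows_backward <- function(dVn, Vn, norms) {
  (dVn - Vn * rowSums(dVn * Vn)) / norms
}

# Gather all (descriptor, class-index) ground-truth pairs from scenes.
collect_region_pairs <- function(scenes, kb) {
  X <- list(); y <- integer(0)
  for (sc in scenes) {
    if (nrow(sc$boxes) == 0) next
    D <- region_descriptors(sc$image, sc$boxes)
    X[[length(X) + 1L]] <- D
    y <- c(y, match(sc$labels, kb$species_ids))
  }
  if (length(X) == 0) stop("no ground-truth regions in the supplied scenes",
                           call. = FALSE)
  list(X = do.call(rbind, X), y = y)
}

#' Train and freeze the teacher region encoder
#'
#' A small region encoder trained briefly on the synthetic corpus with the
#' contrastive objective only, then frozen; it plays the role of the
#' pre-trained teacher whose region-text similarities the student distills.
#'
#' @param scenes Training scenes.
#' @param kb A [build_knowledge_base()] object.
#' @param seed Seed for initialization and batch order.
#' @param epochs,lr Training schedule.
#' @param tau Contrastive temperature.
#' @return A frozen `region_encoder`.
#' @export
make_teacher <- function(scenes, kb, seed = 99, epochs = 15, lr = 0.5, tau = 0.1) {
  fit <- pretrain_region_encoder(scenes, kb, teacher = NULL,
                                 config = alignment_config(
                                   tau = tau, lr = lr, epochs = epochs,
                                   distill_weight = 0, seed = seed))
  fit$encoder
}

#' Alignment training configuration
#'
#' @param tau Contrastive temperature in `(0, 1)`.
#' @param lr SGD learning rate.
#' @param epochs Number of passes over the matched-pair corpus.
#' @param distill_weight Weight of the distillation term.
#' @param seed RNG seed.
#' @param d_out Feature dimension.
#' @return A named list of validated settings.
#' @export
alignment_config <- function(tau = 0.1, lr = 0.5, epochs = 20,
                             distill_weight = 1, seed = 0, d_out = 32) {
  check_tau(tau)
  stopifnot(lr >= 0, epochs >= 1, distill_weight >= 0)
  list(tau = tau, lr = lr, epochs = epochs,
       distill_weight = distill_weight, seed = seed, d_out = d_out)
}

#' Pretrain the student region encoder with contrastive + distillation loss
#'
#' Matched (region, species-text) pairs are drawn from ground-truth boxes;
#' each batch holds one region per species so the other texts in the batch
#' act as negatives. When a frozen `teacher` is supplied, the squared
#' difference between teacher and student matched-pair similarities is
#' added with weight `distill_weight`.
#'
#' @param scenes Training scenes.
#' @param kb Knowledge base supplying encoded text features.
#' @param teacher Frozen `region_encoder` or `NULL` (contrastive only).
#' @param config An [alignment_config()].
#' @return List with the trained `encoder` and a per-epoch `trace` data
#'   frame of contrastive and distillation losses.
#' @export
pretrain_region_encoder <- function(scenes, kb, teacher = NULL,
                                    config = alignment_config()) {
  pairs <- collect_region_pairs(scenes, kb)
  Tn <- normalize_rows(kb$T)$Vn
  classes <- sort(unique(pairs$y))
  by_class <- lapply(classes, function(cl) which(pairs$y == cl))
  enc <- make_region_encoder(ncol(pairs$X), config$d_out, seed = config$seed)
  teach_feats <- if (!is.null(teacher)) {
    normalize_rows(encode_regions(teacher, pairs$X))$Vn
  } else NULL
  n_batches <- max(1L, floor(min(lengths(by_class))))
  trace <- data.frame(epoch = integer(0), contrastive = numeric(0),
                      distillation = numeric(0))
  batch_seeds <- derive_seeds(config$seed + 1, config$epochs)
  for (ep in seq_len(config$epochs)) {
    orders <- with_seed(batch_seeds[ep],
                        lapply(by_class, function(ix) sample(ix, n_batches,
                                                             replace = length(ix) < n_batches)))
    ep_con <- 0; ep_dis <- 0
    for (b in seq_len(n_batches)) {
      idx <- vapply(orders, `[[`, integer(1), b)
      Xb <- pairs$X[idx, , drop = FALSE]
      V <- encode_regions(enc, Xb)
      nr <- normalize_rows(V)
      S <- nr$Vn %*% t(Tn[classes, , drop = FALSE])
      l_con <- contrastive_loss(S, config$tau)
      dS <- contrastive_loss_grad(S, config$tau)
      l_dis <- 0
      if (!is.null(teach_feats) && config$distill_weight > 0) {
        S_t <- teach_feats[idx, , drop = FALSE] %*% t(Tn[classes, , drop = FALSE])
        l_dis <- distillation_loss(diag(S_t), diag(S))
        diag(dS) <- diag(dS) +
          config$distill_weight * distillation_loss_grad(diag(S_t), diag(S))
      }
      if (!is.finite(l_con) || !is.finite(l_dis)) {
        stop(sprintf("alignment pretraining diverged at epoch %d (loss not finite)", ep),
             call. = FALSE)
      }
      dVn <- dS %*% Tn[classes, , drop = FALSE]
      dV <- normalize_rows_backward(dVn, nr$Vn, nr$norms)
      enc$W <- enc$W - config$lr * t(dV) %*% Xb
      enc$b <- enc$b - config$lr * colSums(dV)
      ep_con <- ep_con + l_con
      ep_dis <- ep_dis + l_dis
    }
    trace <- rbind(trace, data.frame(epoch = ep,
                                     contrastive = ep_con / n_batches,
                                     distillation = ep_dis / n_batches))
  }
  list(encoder = enc, trace = trace)
}
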