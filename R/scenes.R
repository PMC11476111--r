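#' Scene specification
#'
#' Parameters of one synthetic camera-trap scene: canvas size, how many
#' animals it contains, how often animals are occluded by one another, how
#' much background clutter is rendered, and a global lighting multiplier.
#' `n_targets = 0` produces an empty shot (no animal, no box), the negative
#' class used by absence testing.
#'
#' @param width,height Canvas size in pixels.
#' @param n_targets Integer `>= 0`, number of animals per scene.
#' @param occlusion_prob Probability in `[0, 1]` that a target is partially
#'   occluded (its box then overlaps another target's box).
#' @param clutter_level Fraction in `[0, 1]` controlling background clutter.
#' @param lighting Global intensity multiplier in `(0, 2]`.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 64, height = 64, n_targets = 3,
                       occlusion_prob = 0.25, clutter_level = 0.3,
                       lighting = 1.0) {
  n_targets <- as.integer(n_targets)
  stopifnot(width >= 16, height >= 16, n_targets >= 0L)
  if (occlusion_prob < 0 || occlusion_prob > 1) {
    stop("occlusion_prob must lie in [0, 1]", call. = FALSE)
  }
  if (clutter_level < 0 || clutter_level > 1) {
    stop("clutter_level must lie in [0, 1]", call. = FALSE)
  }
  if (lighting <= 0 || lighting > 2) {
    stop("lighting must lie in (0, 2]", call. = FALSE)
  }
  structure(list(width = width, height = height, n_targets = n_targets,
                 occlusion_prob = occlusion_prob,
                 clutter_level = clutter_level, lighting = lighting),
            class = "scene_spec")
}

new_annotated_scene <- function(image, boxes, labels, occluded, scene_id) {
  stopifnot(nrow(boxes) == length(labels), length(labels) == length(occluded))
  if (nrow(boxes) > 0) {
    stopifnot(all(boxes[, 3] > boxes[, 1]), all(boxes[, 4] > boxes[, 2]))
    stopifnot(all(boxes[, 1] >= 0), all(boxes[, 2] >= 0),
              all(boxes[, 3] <= ncol(image)), all(boxes[, 4] <= nrow(image)))
  }
  structure(list(image = image, boxes = boxes, labels = as.integer(labels),
                 occluded = as.logical(occluded),
                 scene_id = as.character(scene_id)),
            class = "annotated_scene")
}

empty_boxes <- function() {
  matrix(numeric(0), ncol = 4,
         dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
}

# Ellipse / silhouette masks on a local bw x bh pixel grid ----------------

ellipse_mask <- function(bw, bh, cx, cy, rx, ry) {
  xs <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
  ys <- matrix(seq_len(bh), bh, bw)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

rect_mask <- function(bw, bh, x0, x1, y0, y1) {
  xs <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
  ys <- matrix(seq_len(bh), bh, bw)
  xs >= x0 & xs <= x1 & ys >= y0 & ys <= y1
}

silhouette_mask <- function(shape_family, bw, bh) {
  switch(shape_family,
    "blob" = ellipse_mask(bw, bh, (bw + 1) / 2, (bh + 1) / 2,
                          bw / 2, bh / 2),
    "quadruped-silhouette" = {
      body <- ellipse_mask(bw, bh, bw * 0.48, bh * 0.38, bw * 0.45, bh * 0.30)
      head <- ellipse_mask(bw, bh, bw * 0.88, bh * 0.22, bw * 0.14, bh * 0.16)
      legs <- rect_mask(bw, bh, bw * 0.15, bw * 0.25, bh * 0.55, bh) |
              rect_mask(bw, bh, bw * 0.35, bw * 0.45, bh * 0.55, bh) |
              rect_mask(bw, bh, bw * 0.60, bw * 0.70, bh * 0.55, bh) |
              rect_mask(bw, bh, bw * 0.80, bw * 0.90, bh * 0.55, bh)
      body | head | legs
    },
    "bird-silhouette" = {
      body <- ellipse_mask(bw, bh, bw * 0.45, bh * 0.58, bw * 0.36, bh * 0.30)
      head <- ellipse_mask(bw, bh, bw * 0.74, bh * 0.28, bw * 0.13, bh * 0.15)
      wing <- ellipse_mask(bw, bh, bw * 0.38, bh * 0.42, bw * 0.22, bh * 0.18)
      tail <- rect_mask(bw, bh, 1, bw * 0.18, bh * 0.45, bh * 0.62)
      body | head | wing | tail
    })
}

apply_texture <- function(color_layers, mask, texture, bw, bh) {
  # color_layers: bh x bw x 3 numeric; darkens stripes/spots inside the mask
  if (texture == "striped") {
    period <- max(2, round(bw / 6))
    xs <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
    dark <- (floor(xs / period) %% 2 == 0) & mask
    for (ch in 1:3) color_layers[, , ch][dark] <- color_layers[, , ch][dark] * 0.55
  } else if (texture == "spotted") {
    n_spots <- max(3, round(bw * bh / 40))
    sx <- stats::runif(n_spots, 1, bw)
    sy <- stats::runif(n_spots, 1, bh)
    r <- max(1, min(bw, bh) / 8)
    xs <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
    ys <- matrix(seq_len(bh), bh, bw)
    dark <- matrix(FALSE, bh, bw)
    for (k in seq_len(n_spots)) {
      dark <- dark | ((xs - sx[k])^2 + (ys - sy[k])^2 <= r^2)
    }
    dark <- dark & mask
    for (ch in 1:3) color_layers[, , ch][dark] <- color_layers[, , ch][dark] * 0.45
  }
  color_layers
}

# Place a box of size (w, h) so that it overlaps `anchor` (IoU > 0) and
# stays inside the canvas.
place_overlapping <- function(anchor, w, h, W, H) {
  ov <- stats::runif(1, 0.25, 0.6)
  xmin <- anchor[3] - ov * w
  ylo <- max(0, anchor[2] - h + 2)
  yhi <- min(H - h, anchor[4] - 2)
  ymin <- if (yhi > ylo) stats::runif(1, ylo, yhi) else max(0, min(H - h, anchor[2]))
  xmin <- clamp(xmin, 0, W - w)
  box <- c(xmin, ymin, xmin + w, ymin + h)
  if (box_iou_pair(box, anchor) <= 0) {
    # degenerate clamp: stack directly on the anchor
    box <- c(clamp(anchor[1], 0, W - w), clamp(anchor[2], 0, H - h))
    box <- c(box[1], box[2], box[1] + w, box[2] + h)
  }
  box
}

generate_scene <- function(catalog, spec, seed, scene_id) {
  with_seed(seed, {
    W <- spec$width; H <- spec$height
    # background: muted earth/green base + clutter blobs + sensor noise
    palettes <- matrix(c(92, 104, 62,   110, 96, 70,   84, 92, 84,
                         120, 112, 78,  70, 82, 58), ncol = 3, byrow = TRUE)
    base <- palettes[sample.int(nrow(palettes), 1), ] + stats::rnorm(3, 0, 6)
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- base[ch]
    n_clutter <- round(spec$clutter_level * 14)
    for (k in seq_len(n_clutter)) {
      cw <- stats::runif(1, 4, W / 3); chh <- stats::runif(1, 4, H / 3)
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      shade <- stats::runif(1, 0.7, 1.3)
      x0 <- max(1, round(cx - cw / 2)); x1 <- min(W, round(cx + cw / 2))
      y0 <- max(1, round(cy - chh / 2)); y1 <- min(H, round(cy + chh / 2))
      if (x1 > x0 && y1 > y0) {
        m <- ellipse_mask(x1 - x0 + 1, y1 - y0 + 1,
                          (x1 - x0) / 2 + 1, (y1 - y0) / 2 + 1,
                          (x1 - x0) / 2 + 0.5, (y1 - y0) / 2 + 0.5)
        for (ch in 1:3) {
          patch <- img[y0:y1, x0:x1, ch]
          patch[m] <- patch[m] * shade
          img[y0:y1, x0:x1, ch] <- patch
        }
      }
    }
    img <- img + array(stats::rnorm(H * W * 3, 0, 7), dim = c(H, W, 3))

    n <- spec$n_targets
    boxes <- empty_boxes()
    labels <- integer(0)
    occluded <- logical(0)
    if (n > 0) {
      flags <- stats::runif(n) < spec$occlusion_prob
      if (n == 1L) flags[] <- FALSE
      sp_idx <- sample.int(length(catalog), n, replace = TRUE)
      for (i in seq_len(n)) {
        a <- catalog[[sp_idx[i]]]
        side <- stats::runif(1, a$size_range[1], min(a$size_range[2], min(W, H) - 2))
        aspect <- stats::runif(1, 0.75, 1.35)
        w <- min(W - 1, side)
        h <- min(H - 1, side * aspect)
        need_overlap <- (i >= 2 && flags[i]) || (i == 2 && flags[1])
        if (need_overlap) {
          anchor <- boxes[sample.int(nrow(boxes), 1), ]
          if (i == 2 && flags[1]) anchor <- boxes[1, ]
          box <- place_overlapping(anchor, w, h, W, H)
        } else {
          xmin <- stats::runif(1, 0, W - w)
          ymin <- stats::runif(1, 0, H - h)
          box <- c(xmin, ymin, xmin + w, ymin + h)
        }
        boxes <- rbind(boxes, box)
        labels <- c(labels, a$species_id)
        occluded <- c(occluded, flags[i])

        # render: silhouette + texture + camouflage blending
        x0 <- max(1, floor(box[1]) + 1); x1 <- min(W, ceiling(box[3]))
        y0 <- max(1, floor(box[2]) + 1); y1 <- min(H, ceiling(box[4]))
        bw <- x1 - x0 + 1; bh <- y1 - y0 + 1
        mask <- silhouette_mask(a$shape_family, bw, bh)
        bg_patch <- img[y0:y1, x0:x1, , drop = FALSE]
        bg_mean <- apply(bg_patch, 3, mean)
        col <- a$base_color + stats::rnorm(3, 0, 10)
        col <- (1 - a$camouflage_affinity) * col + a$camouflage_affinity * bg_mean
        layers <- array(0, dim = c(bh, bw, 3))
        for (ch in 1:3) layers[, , ch] <- col[ch]
        layers <- apply_texture(layers, mask, a$texture, bw, bh)
        for (ch in 1:3) {
          patch <- img[y0:y1, x0:x1, ch]
          patch[mask] <- layers[, , ch][mask] + stats::rnorm(sum(mask), 0, 4)
          img[y0:y1, x0:x1, ch] <- patch
        }
      }
      rownames(boxes) <- NULL
      colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")

      # vegetation band over every occluded target
      for (i in which(occluded)) {
        b <- boxes[i, ]
        x0 <- max(1, round(b[1] + 0.30 * (b[3] - b[1])))
        x1 <- min(W, round(b[1] + 0.55 * (b[3] - b[1])))
        y0 <- max(1, floor(b[2]) + 1); y1 <- min(H, ceiling(b[4]))
        if (x1 > x0 && y1 > y0) {
          for (ch in 1:3) {
            img[y0:y1, x0:x1, ch] <- base[ch] * 0.85 +
              matrix(stats::rnorm((y1 - y0 + 1) * (x1 - x0 + 1), 0, 5),
                     y1 - y0 + 1, x1 - x0 + 1)
          }
        }
      }
    }
    img <- clamp(img * spec$lighting, 0, 255)
    img <- round(img)
    storage.mode(img) <- "integer"
    new_annotated_scene(img, boxes, labels, occluded, scene_id)
  })
}

#' Generate a synthetic annotated dataset
#'
#' Produces `n_scenes` reproducible scenes: multi-species silhouettes with
#' small, occluded, and camouflaged targets over cluttered backgrounds,
#' each with exact bounding-box annotations. The same `(catalog, spec,
#' seed)` triple always yields byte-identical images and annotations.
#'
#' @param catalog Non-empty list of [species_archetype()] objects.
#' @param n_scenes Number of scenes, `>= 1`.
#' @param spec A [scene_spec()] template applied to every scene.
#' @param seed Integer seed controlling all randomness.
#' @return A list of `annotated_scene` objects.
#' @export
generate_dataset <- function(catalog, n_scenes, spec = scene_spec(), seed = 1) {
  validate_catalog(catalog)
  stopifnot(inherits(spec, "scene_spec"), n_scenes >= 1)
  seeds <- derive_seeds(seed, n_scenes)
  lapply(seq_len(n_scenes), function(i) {
    generate_scene(catalog, spec, seeds[i], sprintf("scene-%06d", i))
  })
}

#' Split a dataset into train/validation/test
#'
#' Seed-deterministic shuffle followed by a floor-based partition:
#' validation and test sizes are `floor(n * fraction)` and the remainder
#' goes to the training split.
#'
#' @param scenes List of scenes (or any list).
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer shuffle seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(scenes, fractions = c(0.7, 0.15, 0.15), seed = 0) {
  stopifnot(length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n <- length(scenes)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  idx <- with_seed(seed, sample.int(n))
  list(train = scenes[idx[seq_len(n_train)]],
       val = scenes[idx[seq_len(n_val) + n_train]],
       test = scenes[idx[seq_len(n_test) + n_train + n_val]])
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("<annotated_scene %s: %dx%d px, %d target(s), %d occluded>\n",
              x$scene_id, ncol(x$image), nrow(x$image),
              nrow(x$boxes), sum(x$occluded)))
  invisible(x)
}
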