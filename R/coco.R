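#' Write scenes as PNG images plus a COCO-style annotation file
#'
#' Boxes are stored internally as continuous `(xmin, ymin, xmax, ymax)`
#' with a top-left origin and serialized in the COCO `[x, y, width,
#' height]` convention. Reading back reproduces boxes, labels and image
#' references exactly.
#'
#' @param scenes List of `annotated_scene` objects.
#' @param dir Output directory; images go to `dir/images/`, annotations to
#'   `dir/annotations.json`.
#' @param catalog Optional catalog supplying category names.
#' @return `write_coco` returns the annotation path invisibly; `read_coco`
#'   returns a list of `annotated_scene` objects.
#' @export
write_coco <- function(scenes, dir, catalog = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  images <- vector("list", length(scenes))
  annotations <- list()
  ann_id <- 1L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    stopifnot(inherits(sc, "annotated_scene"))
    fn <- paste0(sc$scene_id, ".png")
    png::writePNG(aperm(array(sc$image / 255, dim = dim(sc$image)),
                        c(1, 2, 3)),
                  file.path(dir, "images", fn))
    images[[i]] <- list(id = i, file_name = fn,
                        width = ncol(sc$image), height = nrow(sc$image),
                        scene_id = sc$scene_id)
    if (nrow(sc$boxes) > 0) {
      for (k in seq_len(nrow(sc$boxes))) {
        b <- sc$boxes[k, ]
        annotations[[length(annotations) + 1L]] <- list(
          id = ann_id, image_id = i,
          category_id = sc$labels[k],
          bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
          area = (b[3] - b[1]) * (b[4] - b[2]),
          iscrowd = 0L, occluded = sc$occluded[k])
        ann_id <- ann_id + 1L
      }
    }
  }
  cat_ids <- sort(unique(unlist(lapply(scenes, function(s) s$labels))))
  if (!is.null(catalog)) {
    categories <- lapply(catalog, function(a) {
      list(id = a$species_id, name = a$name, supercategory = "animal")
    })
  } else {
    categories <- lapply(cat_ids, function(id) {
      list(id = id, name = sprintf("species-%d", id), supercategory = "animal")
    })
  }
  path <- file.path(dir, "annotations.json")
  jsonlite::write_json(
    list(images = images, annotations = annotations, categories = categories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @param path Path to a COCO `annotations.json` written by [write_coco()]
#'   (images are resolved relative to its directory).
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed COCO JSON at %s: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (!all(c("images", "annotations") %in% names(doc))) {
    stop("malformed COCO JSON: missing images/annotations arrays", call. = FALSE)
  }
  img_dir <- file.path(dirname(path), "images")
  ann_by_img <- split(doc$annotations,
                      vapply(doc$annotations, function(a) a$image_id, numeric(1)))
  scenes <- vector("list", length(doc$images))
  for (i in seq_along(doc$images)) {
    im <- doc$images[[i]]
    fp <- file.path(img_dir, im$file_name)
    if (!file.exists(fp)) {
      stop(sprintf("missing image file for record %d (%s)", i, im$file_name),
           call. = FALSE)
    }
    px <- png::readPNG(fp)
    img <- round(px * 255)
    storage.mode(img) <- "integer"
    anns <- ann_by_img[[as.character(im$id)]]
    boxes <- empty_boxes()
    labels <- integer(0)
    occluded <- logical(0)
    for (a in anns) {
      bb <- unlist(a$bbox)
      if (length(bb) != 4 || bb[3] <= 0 || bb[4] <= 0) {
        stop(sprintf("invalid zero-size box in annotation record %d", a$id),
             call. = FALSE)
      }
      boxes <- rbind(boxes, c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]))
      labels <- c(labels, as.integer(a$category_id))
      occluded <- c(occluded, isTRUE(a$occluded))
    }
    rownames(boxes) <- NULL
    colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
    scenes[[i]] <- new_annotated_scene(img, boxes, labels, occluded,
                                       im$scene_id %||% tools::file_path_sans_ext(im$file_name))
  }
  scenes
}

#' Write detections as a COCO results array
#'
#' @param detections Data frame with columns `image_id`, `label`, `score`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(detections, path) {
  recs <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(image_id = d$image_id, category_id = d$label,
         bbox = c(d$xmin, d$ymin, d$xmax - d$xmin, d$ymax - d$ymin),
         score = d$score)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
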