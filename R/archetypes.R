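#' Species archetype
#'
#' An archetype describes the synthetic appearance of one species: its
#' silhouette family, base colour, texture, the range of box side lengths it
#' can occupy in a scene, and how strongly it camouflages (probability that
#' its colour is blended toward the local background).
#'
#' @param species_id Integer id, unique within a catalog, `>= 0`.
#' @param name Species name used in descriptors and COCO categories.
#' @param shape_family One of `"blob"`, `"quadruped-silhouette"`,
#'   `"bird-silhouette"`.
#' @param base_color Length-3 RGB triple in `[0, 255]`.
#' @param texture One of `"plain"`, `"striped"`, `"spotted"`.
#' @param size_range Numeric `(min_px, max_px)` box side lengths, min `>= 4`.
#' @param camouflage_affinity Probability in `[0, 1]` that a rendered
#'   individual is alpha-blended toward the background patch it sits on.
#'
#' @return An object of class `species_archetype`.
#' @export
species_archetype <- function(species_id, name, shape_family, base_color,
                              texture = "plain", size_range = c(10, 28),
                              camouflage_affinity = 0) {
  species_id <- as.integer(species_id)
  if (is.na(species_id) || species_id < 0L) {
    stop("species_id must be an integer >= 0", call. = FALSE)
  }
  shape_family <- match.arg(shape_family,
    c("blob", "quadruped-silhouette", "bird-silhouette"))
  texture <- match.arg(texture, c("plain", "striped", "spotted"))
  base_color <- as.numeric(base_color)
  stopifnot(length(base_color) == 3L, all(base_color >= 0), all(base_color <= 255))
  size_range <- as.numeric(size_range)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  if (size_range[1] < 4) {
    stop("size_range minimum must be >= 4 px", call. = FALSE)
  }
  if (camouflage_affinity < 0 || camouflage_affinity > 1) {
    stop("camouflage_affinity must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(species_id = species_id, name = as.character(name),
         shape_family = shape_family, base_color = base_color,
         texture = texture, size_range = size_range,
         camouflage_affinity = camouflage_affinity),
    class = "species_archetype")
}

#' Default synthetic species catalog
#'
#' Eleven invented archetypes spanning the silhouette families, textures,
#' size classes and camouflage levels the generator supports; toy
#' experiments typically use the first few.
#'
#' @param n Number of species to return (1-11).
#' @return A list of [species_archetype()] objects.
#' @export
default_catalog <- function(n = 11) {
  stopifnot(n >= 1, n <= 11)
  specs <- list(
    list("mist panda",        "quadruped-silhouette", c(235, 235, 235), "spotted", c(18, 38), 0.05),
    list("ember fox",         "quadruped-silhouette", c(200,  90,  30), "plain",   c(12, 26), 0.25),
    list("reed heron",        "bird-silhouette",      c( 70, 110, 180), "plain",   c( 8, 18), 0.15),
    list("shale macaque",     "blob",                 c(150, 120,  90), "plain",   c(10, 24), 0.45),
    list("banded civet",      "quadruped-silhouette", c(120, 110,  60), "striped", c(10, 22), 0.35),
    list("dusk porcupine",    "blob",                 c( 60,  50,  40), "spotted", c( 8, 18), 0.40),
    list("ghost serow",       "quadruped-silhouette", c( 90, 100,  80), "plain",   c(16, 34), 0.60),
    list("ridge deer",        "quadruped-silhouette", c(160, 120,  70), "spotted", c(16, 36), 0.30),
    list("thorn pheasant",    "bird-silhouette",      c(180,  60,  60), "striped", c( 6, 14), 0.20),
    list("moss takin",        "blob",                 c(140, 130,  70), "plain",   c(20, 40), 0.50),
    list("gold marten",       "quadruped-silhouette", c(220, 180,  60), "plain",   c( 8, 18), 0.10)
  )
  lapply(seq_len(n), function(i) {
    s <- specs[[i]]
    species_archetype(i - 1L, s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]])
  })
}

validate_catalog <- function(catalog) {
  if (length(catalog) == 0L) {
    stop("catalog must contain at least one species archetype", call. = FALSE)
  }
  ids <- vapply(catalog, function(a) a$species_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("species_id values must be unique within a catalog", call. = FALSE)
  }
  invisible(catalog)
}

catalog_ids <- function(catalog) {
  vapply(catalog, function(a) a$species_id, integer(1))
}

#' Write or read a species catalog as JSON
#'
#' @param catalog List of [species_archetype()] objects.
#' @param path File path of the catalog JSON.
#' @return `read_catalog` returns a list of archetypes; `write_catalog`
#'   returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  recs <- lapply(catalog, function(a) {
    list(species_id = a$species_id, name = a$name,
         shape_family = a$shape_family, base_color = a$base_color,
         texture = a$texture, size_range = a$size_range,
         camouflage_affinity = a$camouflage_affinity)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  catalog <- lapply(recs, function(r) {
    species_archetype(r$species_id, r$name, r$shape_family, unlist(r$base_color),
                      r$texture, unlist(r$size_range), r$camouflage_affinity)
  })
  validate_catalog(catalog)
  catalog
}
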