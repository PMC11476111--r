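#' Build templated species descriptions
#'
#' Renders one textual concept descriptor per species from a deterministic
#' template set. Every rendered text mentions the species' colour, shape
#' family, texture, size class and a distinctive mark, mirroring the kind
#' of attribute phrases an expert knowledge base holds.
#'
#' @param catalog Non-empty list of [species_archetype()] objects.
#' @param templates Character vector of glue-style templates containing the
#'   placeholders `{name}`, `{color}`, `{shape}`, `{texture}`, `{size}`,
#'   `{mark}` and `{habitat}`.
#' @param seed Integer seed controlling template and phrase choice.
#' @return A list of `concept_descriptor` objects with fields
#'   `species_id`, `attributes` and `rendered_text`.
#' @export
build_descriptions <- function(catalog, templates = default_templates(), seed = 0) {
  validate_catalog(catalog)
  stopifnot(length(templates) >= 1)
  marks <- c("an upright tail", "a pale throat patch", "dark eye rings",
             "a ridged back", "white ear tufts", "a banded muzzle",
             "a crested crown", "a stubby tail", "long curved claws",
             "a shoulder stripe", "a frosted rump patch")
  habitats <- c("dense bamboo understory", "open rocky scree",
                "riverine reed beds", "mossy conifer forest",
                "subalpine meadow edges", "shaded ravine thickets")
  seeds <- derive_seeds(seed, length(catalog))
  lapply(seq_along(catalog), function(i) {
    a <- catalog[[i]]
    with_seed(seeds[i], {
      attrs <- list(
        color = color_word(a$base_color),
        shape = sub("-silhouette", "", a$shape_family),
        texture = a$texture,
        size = size_class_word(mean(a$size_range)),
        mark = marks[(a$species_id %% length(marks)) + 1L],
        habitat = sample(habitats, 1))
      tmpl <- templates[sample.int(length(templates), 1)]
      txt <- tmpl
      for (key in c("name", names(attrs))) {
        val <- if (key == "name") a$name else attrs[[key]]
        txt <- gsub(paste0("{", key, "}"), val, txt, fixed = TRUE)
      }
      structure(list(species_id = a$species_id, attributes = attrs,
                     rendered_text = txt),
                class = "concept_descriptor")
    })
  })
}

#' @rdname build_descriptions
#' @export
default_templates <- function() {
  c("the {name} is a {size} {shape} animal with {texture} {color} fur, recognisable by {mark}, usually seen near {habitat}",
    "a {size} {color} {shape} with {texture} coat markings and {mark}, favouring {habitat}",
    "{name}: {size} body, {shape} outline, {texture} {color} pelage, distinctive {mark}, habitat {habitat}")
}

color_word <- function(rgb) {
  palette <- rbind(black = c(40, 40, 40), white = c(230, 230, 230),
                   grey = c(140, 140, 140), brown = c(150, 110, 70),
                   russet = c(190, 90, 40), golden = c(215, 175, 70),
                   olive = c(120, 120, 70), slate = c(90, 100, 110),
                   blue = c(70, 110, 180), crimson = c(180, 60, 60))
  d <- colSums((t(palette) - rgb)^2)
  names(which.min(d))
}

size_class_word <- function(mean_side) {
  if (mean_side < 14) "small" else if (mean_side < 26) "medium-sized" else "large"
}

# Hashed bag-of-tokens embedding for description texts -------------------

hash_token <- function(token, d) {
  codes <- utf8ToInt(token)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 1048573
  (h %% d) + 1L
}

#' Embed description texts as fixed-dimension vectors
#'
#' Deterministic hashed bag-of-tokens embedding: each lower-cased token of
#' the rendered text increments one of `d` buckets, and the resulting count
#' vector is L2-normalized. Serves as the description vectors S.
#'
#' @param descriptors List from [build_descriptions()].
#' @param d Embedding dimension.
#' @return An `N x d` numeric matrix.
#' @export
embed_descriptions <- function(descriptors, d = 64) {
  stopifnot(d >= 1)
  S <- t(vapply(descriptors, function(dd) {
    toks <- strsplit(tolower(gsub("[^a-z ]", "", tolower(dd$rendered_text))),
                     " +")[[1]]
    toks <- toks[nzchar(toks)]
    v <- numeric(d)
    for (tk in toks) {
      idx <- hash_token(tk, d)
      v[idx] <- v[idx] + 1
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }, numeric(d)))
  rownames(S) <- vapply(descriptors, function(x) as.character(x$species_id), "")
  S
}

#' Embed class labels
#'
#' Default one-hot-padded scheme: row `n` (0-based class `n - 1`) has a 1
#' at position `n` and 0 elsewhere, padded with zeros up to dimension `d`.
#' A seeded linear projection is available when `d < N`.
#'
#' @param N Number of classes.
#' @param d Target dimension (`d >= N` unless a projection is requested).
#' @param projection Either `"one-hot"` (default, requires `d >= N`) or
#'   `"random"` (seeded Gaussian projection of the one-hot rows).
#' @param seed Seed for the random projection.
#' @return An `N x d` matrix with distinct rows.
#' @export
embed_labels <- function(N, d, projection = c("one-hot", "random"), seed = 0) {
  projection <- match.arg(projection)
  stopifnot(N >= 1, d >= 1)
  if (projection == "one-hot") {
    if (d < N) {
      stop(sprintf("label dimension d = %d < N = %d classes; configure a projection",
                   d, N), call. = FALSE)
    }
    C <- matrix(0, N, d)
    C[cbind(seq_len(N), seq_len(N))] <- 1
    C
  } else {
    P <- rnorm_matrix(N, d, seed, sd = 1 / sqrt(d))
    P
  }
}

#' Compose knowledge vectors E = S + C
#'
#' Plain elementwise vector addition of the embedded description vectors
#' and embedded label vectors; no hidden normalization.
#'
#' @param S,C `N x d` matrices of identical shape.
#' @return The `N x d` matrix `S + C`.
#' @export
compose_knowledge <- function(S, C) {
  if (!all(dim(S) == dim(C))) {
    stop(sprintf("shape mismatch: S is %dx%d but C is %dx%d",
                 nrow(S), ncol(S), nrow(C), ncol(C)), call. = FALSE)
  }
  S + C
}

#' Frozen text encoder
#'
#' A small deterministic language encoder standing in for a pre-trained
#' text tower: a seeded Gaussian linear map followed by tanh. Frozen by
#' construction (identical seeds give bitwise-identical encoders).
#'
#' @param d_in Input (knowledge vector) dimension.
#' @param d_out Output feature dimension.
#' @param seed Seed freezing the weights.
#' @return An object of class `text_encoder`.
#' @export
make_text_encoder <- function(d_in, d_out = 32, seed = 42) {
  A <- rnorm_matrix(d_out, d_in, seed, sd = 1 / sqrt(d_in))
  b <- rnorm_matrix(1, d_out, seed + 1, sd = 0.1)[1, ]
  structure(list(A = A, b = b, d_in = d_in, d_out = d_out), class = "text_encoder")
}

#' Encode knowledge vectors into text features T
#'
#' @param E `N x d` knowledge matrix.
#' @param encoder A [make_text_encoder()] object whose `d_in` matches
#'   `ncol(E)`.
#' @return An `N x d_out` feature matrix.
#' @export
encode_texts <- function(E, encoder) {
  stopifnot(inherits(encoder, "text_encoder"))
  if (ncol(E) != encoder$d_in) {
    stop(sprintf("encoder expects dimension %d, got %d", encoder$d_in, ncol(E)),
         call. = FALSE)
  }
  T_out <- tanh(sweep(E %*% t(encoder$A), 2, encoder$b, "+"))
  assert_finite(T_out, "encoded text features")
  rownames(T_out) <- rownames(E)
  T_out
}

#' Build a complete species knowledge base
#'
#' Runs description templating, description/label embedding, knowledge
#' composition `E = S + C`, and text encoding `T = L(E)` in one call.
#'
#' @param catalog List of [species_archetype()] objects.
#' @param d Shared embedding dimension for S, C and E (must be `>= N`).
#' @param d_enc Encoded text feature dimension.
#' @param seed Seed for templating and the frozen encoder.
#' @return An object of class `knowledge_base` with fields `N`,
#'   `species_ids`, `names`, `descriptors`, `S`, `C`, `E`, `T`, `encoder`.
#' @export
build_knowledge_base <- function(catalog, d = 64, d_enc = 32, seed = 42) {
  validate_catalog(catalog)
  descriptors <- build_descriptions(catalog, seed = seed)
  S <- embed_descriptions(descriptors, d = d)
  C <- embed_labels(length(catalog), d = d)
  E <- compose_knowledge(S, C)
  encoder <- make_text_encoder(d, d_enc, seed = seed)
  T_feat <- encode_texts(E, encoder)
  structure(list(N = length(catalog),
                 species_ids = catalog_ids(catalog),
                 names = vapply(catalog, function(a) a$name, ""),
                 descriptors = descriptors,
                 S = S, C = C, E = E, T = T_feat, encoder = encoder),
            class = "knowledge_base")
}

#' Serialize / restore a knowledge base as JSON
#'
#' @param kb A `knowledge_base`.
#' @param path JSON file path.
#' @return `read_knowledge_base` returns a `knowledge_base`;
#'   `write_knowledge_base` returns `path` invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  out <- list(
    N = kb$N, species_ids = kb$species_ids, names = kb$names,
    descriptors = lapply(kb$descriptors, unclass),
    S = kb$S, C = kb$C, E = kb$E, T = kb$T,
    encoder = list(A = kb$encoder$A, b = kb$encoder$b,
                   d_in = kb$encoder$d_in, d_out = kb$encoder$d_out))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- structure(list(A = doc$encoder$A, b = doc$encoder$b,
                        d_in = doc$encoder$d_in, d_out = doc$encoder$d_out),
                   class = "text_encoder")
  descs <- lapply(seq_len(nrow(doc$descriptors)), function(i) {
    structure(list(species_id = doc$descriptors$species_id[i],
                   attributes = as.list(doc$descriptors$attributes[i, ]),
                   rendered_text = doc$descriptors$rendered_text[i]),
              class = "concept_descriptor")
  })
  structure(list(N = doc$N, species_ids = doc$species_ids, names = doc$names,
                 descriptors = descs, S = doc$S, C = doc$C, E = doc$E,
                 T = doc$T, encoder = enc),
            class = "knowledge_base")
}
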