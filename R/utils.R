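# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stable row-wise softmax with max subtraction.
softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Derive a stream of child seeds from one user seed; keeps every derived
# seed a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a local RNG seeded with `seed`, restoring global state.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seeded Gaussian matrix used for frozen/initial weights.
rnorm_matrix <- function(nrow, ncol, seed, sd = 1) {
  with_seed(seed, matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
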