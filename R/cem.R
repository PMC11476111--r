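#' Concept enhancement module parameters
#'
#' Single-head scaled dot-product cross-attention from image features onto
#' text (concept) features, a residual connection, and a residual two-layer
#' feedforward network with tanh between the layers. The attention output
#' projection and the FFN output layer are zero-initialized, so a freshly
#' constructed module is exactly the identity on its image-feature input.
#'
#' @param d Image/text feature dimension (must be even, for the
#'   basal/capsule split of the output).
#' @param d_attn Attention projection dimension.
#' @param d_hidden FFN hidden width.
#' @param seed Initialization seed for the query/key/value projections and
#'   FFN input layer.
#' @return An object of class `cem_params`.
#' @export
cem_init <- function(d = 32, d_attn = 16, d_hidden = d, seed = 0) {
  stopifnot(d_attn > 0, d %% 2 == 0)
  sd0 <- 1 / sqrt(d)
  structure(list(
    W_q = rnorm_matrix(d, d_attn, seed, sd0),
    W_k = rnorm_matrix(d, d_attn, seed + 1, sd0),
    W_v = rnorm_matrix(d, d_attn, seed + 2, sd0),
    W_o = matrix(0, d_attn, d),
    W_1 = rnorm_matrix(d, d_hidden, seed + 3, sd0),
    b_1 = numeric(d_hidden),
    W_2 = matrix(0, d_hidden, d),
    b_2 = numeric(d),
    d = d, d_attn = d_attn, d_hidden = d_hidden), class = "cem_params")
}

#' Cross-attention with residual connection
#'
#' `V' = V + CA(W_q V, W_k T, W_v T)`: every image feature row queries the
#' concept (text) rows; attention weights are a row-wise softmax of the
#' scaled dot products, so concepts more related to a region receive
#' higher weight.
#'
#' @param V `n x d` image feature matrix.
#' @param T_i `m x d` concept/text feature matrix, `m >= 1`.
#' @param params A [cem_init()] object.
#' @return `n x d` matrix `V'` with the `n x m` attention weights attached
#'   as attribute `"attention"` and forward intermediates as `"cache"`.
#' @export
cross_attend <- function(V, T_i, params) {
  stopifnot(inherits(params, "cem_params"))
  if (is.null(dim(T_i))) T_i <- matrix(T_i, nrow = 1)
  if (nrow(T_i) == 0) {
    stop("no concepts to attend over (T has zero rows)", call. = FALSE)
  }
  if (ncol(V) != params$d || ncol(T_i) != params$d) {
    stop(sprintf("feature dimension mismatch: expected %d", params$d),
         call. = FALSE)
  }
  Q <- V %*% params$W_q
  K <- T_i %*% params$W_k
  Vv <- T_i %*% params$W_v
  logits <- (Q %*% t(K)) / sqrt(params$d_attn)
  A <- softmax_rows(logits)
  O <- A %*% Vv
  out <- V + O %*% params$W_o
  attr(out, "attention") <- A
  attr(out, "cache") <- list(Q = Q, K = K, Vv = Vv, A = A, O = O, V = V, T = T_i)
  out
}

#' Full concept enhancement forward pass
#'
#' `[V_bas, V_cap] = V' + FFN(V')` where `V'` is the cross-attention
#' output; the two named components are the even split of the residual FFN
#' output along the feature axis and re-concatenate to the module output.
#'
#' @inheritParams cross_attend
#' @return A list with `out` (`n x d`), the split halves `V_bas` and
#'   `V_cap`, the attention weights, and a `cache` for the backward pass.
#' @export
cem_forward <- function(V, T_i, params) {
  Vp <- cross_attend(V, T_i, params)
  cache_att <- attr(Vp, "cache")
  A <- attr(Vp, "attention")
  attributes(Vp) <- list(dim = dim(Vp))
  H <- sweep(Vp %*% params$W_1, 2, params$b_1, "+")
  Z <- tanh(H)
  FFN <- sweep(Z %*% params$W_2, 2, params$b_2, "+")
  out <- Vp + FFN
  half <- params$d / 2
  list(out = out,
       V_bas = out[, seq_len(half), drop = FALSE],
       V_cap = out[, half + seq_len(half), drop = FALSE],
       attention = A,
       cache = list(att = cache_att, Vp = Vp, Z = Z))
}

#' Backward pass of the concept enhancement module
#'
#' Analytic gradients of a scalar loss with respect to every parameter,
#' the image features and the text features, given `dL/d out`.
#'
#' @param d_out `n x d` upstream gradient.
#' @param fwd The list returned by [cem_forward()].
#' @param params The `cem_params` used in the forward pass.
#' @return List with `dV`, `dT`, and `grads` (one entry per parameter).
#' @export
cem_backward <- function(d_out, fwd, params) {
  cache <- fwd$cache
  Vp <- cache$Vp; Z <- cache$Z
  att <- cache$att
  # FFN residual: out = Vp + tanh(Vp W1 + b1) W2 + b2
  dVp <- d_out
  dW_2 <- t(Z) %*% d_out
  db_2 <- colSums(d_out)
  dZ <- d_out %*% t(params$W_2)
  dH <- dZ * (1 - Z^2)
  dW_1 <- t(Vp) %*% dH
  db_1 <- colSums(dH)
  dVp <- dVp + dH %*% t(params$W_1)
  # attention residual: Vp = V + (A Vv) W_o
  dV <- dVp
  dO <- dVp %*% t(params$W_o)
  dW_o <- t(att$O) %*% dVp
  dA <- dO %*% t(att$Vv)
  dVv <- t(att$A) %*% dO
  dLogits <- att$A * (dA - rowSums(dA * att$A))
  scale <- 1 / sqrt(params$d_attn)
  dQ <- (dLogits %*% att$K) * scale
  dK <- (t(dLogits) %*% att$Q) * scale
  dW_q <- t(att$V) %*% dQ
  dW_k <- t(att$T) %*% dK
  dW_v <- t(att$T) %*% dVv
  dV <- dV + dQ %*% t(params$W_q)
  dT <- dK %*% t(params$W_k) + dVv %*% t(params$W_v)
  list(dV = dV, dT = dT,
       grads = list(W_q = dW_q, W_k = dW_k, W_v = dW_v, W_o = dW_o,
                    W_1 = dW_1, b_1 = db_1, W_2 = dW_2, b_2 = db_2))
}

# SGD step over all CEM parameters.
cem_update <- function(params, grads, lr) {
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}
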