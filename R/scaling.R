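#' Learnable scale factor state
#'
#' The continuous feature scaling state: a scalar `alpha` in `(0, 1]` that
#' serves both as the softmax temperature replacement in the cosine
#' classifier and as the feature rescaling factor `1/alpha`, plus its SGD
#' learning rate and learnability flag. `alpha` is clamped to
#' `(1e-3, 1]` after every update.
#'
#' @param alpha Initial value in `(0, 1]`; 0.9 is the standard setting.
#' @param eta Learning rate for the gradient update `alpha <- alpha - eta
#'   * dL/dalpha`.
#' @param learnable Whether updates are applied.
#' @return An object of class `scale_state`.
#' @export
scale_state <- function(alpha = 0.9, eta = 0.01, learnable = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(eta > 0)
  structure(list(alpha = alpha, eta = eta, learnable = isTRUE(learnable)),
            class = "scale_state")
}

ALPHA_EPS <- 1e-3

#' L2-normalize feature rows onto the unit hypersphere
#'
#' @param V `n x d` matrix with no zero rows.
#' @return Matrix with every row scaled to unit L2 norm.
#' @export
l2_normalize <- function(V) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  normalize_rows(V)$Vn
}

#' Cosine similarity as an inner product of unit vectors
#'
#' For unit-norm inputs the cosine reduces to the plain dot product;
#' inputs whose norm deviates from 1 by more than `1e-6` are rejected.
#'
#' @param v_norm,i_norm Unit-norm numeric vectors.
#' @return The scalar inner product.
#' @export
cosine_similarity <- function(v_norm, i_norm) {
  if (abs(sqrt(sum(v_norm^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(i_norm^2)) - 1) > 1e-6) {
    stop("cosine_similarity expects unit-norm inputs", call. = FALSE)
  }
  sum(v_norm * i_norm)
}

#' Class probabilities from image-text cosine similarity
#'
#' `p(y = i | x) = exp(cos(t_i, f) / alpha) / sum_j exp(cos(t_j, f) /
#' alpha)`, with the learnable scale factor `alpha` in the temperature
#' slot: smaller `alpha` sharpens the distribution.
#'
#' @param f Image feature vector (any nonzero norm).
#' @param T_feats `K x d` class text feature matrix.
#' @param scale A [scale_state()].
#' @return A probability vector over the `K` classes.
#' @export
class_probabilities <- function(f, T_feats, scale) {
  stopifnot(inherits(scale, "scale_state"))
  if (scale$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  cosines <- as.numeric(normalize_rows(T_feats)$Vn %*%
                          (f / sqrt(sum(f^2))))
  softmax_vec(cosines / scale$alpha)
}

#' Analytic gradient of the cross-entropy loss with respect to alpha
#'
#' For `L = -log p(y = true | x)` with [class_probabilities()] logits
#' `cos_i / alpha`, `dL/dalpha = sum_i (p_i - y_i) (-cos_i / alpha^2)`.
#'
#' @inheritParams class_probabilities
#' @param y_index Index of the true class.
#' @return Scalar `dL/dalpha`.
#' @export
class_prob_alpha_grad <- function(f, T_feats, y_index, scale) {
  cosines <- as.numeric(normalize_rows(T_feats)$Vn %*%
                          (f / sqrt(sum(f^2))))
  p <- softmax_vec(cosines / scale$alpha)
  y <- numeric(length(p)); y[y_index] <- 1
  sum((p - y) * (-cosines / scale$alpha^2))
}

#' Scale normalized features by 1/alpha
#'
#' `V_scaled = (1 / alpha) * V_norm`; with the standard `alpha = 0.9` every
#' output row has norm `1/0.9 ~ 1.111`.
#'
#' @param V_norm Row-normalized feature matrix.
#' @param scale A [scale_state()].
#' @return The rescaled matrix.
#' @export
scale_features <- function(V_norm, scale) {
  stopifnot(inherits(scale, "scale_state"))
  if (scale$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  V_norm / scale$alpha
}

#' Gradient update of the scale factor
#'
#' `alpha' = clamp(alpha - eta * grad, 1e-3, 1]`; other fields unchanged.
#'
#' @param scale A [scale_state()] with `learnable = TRUE`.
#' @param grad Finite scalar `dL/dalpha`.
#' @return The updated `scale_state`.
#' @export
update_scale <- function(scale, grad) {
  stopifnot(inherits(scale, "scale_state"))
  if (!scale$learnable) {
    stop("scale factor is not learnable", call. = FALSE)
  }
  if (!is.finite(grad)) {
    stop("non-finite gradient for alpha", call. = FALSE)
  }
  scale$alpha <- clamp(scale$alpha - scale$eta * grad, ALPHA_EPS, 1)
  scale
}
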