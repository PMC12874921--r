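# Feature fusion and classification: soft attention over the three projected
# modalities, bidirectional cross-attention with residuals between the drug
# and the protein, and the MLP classifier head.

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Initialize soft-attention parameters
#'
#' A two-layer MLP with Tanh hidden activation scoring the concatenation of
#' the projected modality vectors; its three logits are softmax-normalized
#' into modality weights.
#'
#' @param proj_dim Shared projection width.
#' @param hidden_dim Hidden width of the scorer (128 in the reference setup).
#' @param n_modalities Number of modalities fused (3).
#' @return List with `W1`, `b1`, `W2`, `b2`.
#' @export
soft_attention_params <- function(proj_dim, hidden_dim = 128L,
                                  n_modalities = 3L) {
  d_in <- proj_dim * n_modalities
  # the scoring head starts at zero so fusion begins with exactly uniform
  # modality weights; a random gate would impose an arbitrary, systematic
  # modality bias before any signal is seen
  list(W1 = matrix(stats::rnorm(d_in * hidden_dim, sd = sqrt(2 / d_in)),
                   d_in, hidden_dim),
       b1 = matrix(0, 1L, hidden_dim),
       W2 = matrix(0, hidden_dim, n_modalities),
       b2 = matrix(0, 1L, n_modalities))
}

#' Fuse modality vectors with soft attention
#'
#' Computes `alpha = softmax(MLP([v_1; v_2; ...]))` and returns the convex
#' combination `sum_m alpha_m v_m` along with the weights (logged for
#' modality-contribution analysis).
#'
#' @param modality_vectors List of equal-length numeric vectors (one per
#'   modality, in a fixed order).
#' @param params Parameters from [soft_attention_params()] sized for
#'   `length(modality_vectors)` modalities.
#' @return List with `fused` (vector) and `weights` (simplex vector).
#' @export
soft_attention_fuse <- function(modality_vectors, params) {
  stopifnot(is.list(modality_vectors), length(modality_vectors) >= 1L)
  d <- unique(vapply(modality_vectors, length, 1L))
  if (length(d) != 1L) stop("modality vectors must share the projection dim")
  x <- matrix(unlist(modality_vectors), nrow = 1L)
  if (ncol(x) != nrow(params$W1)) stop("scorer input width mismatch")
  h <- tanh(x %*% params$W1 + as.numeric(params$b1))
  logits <- as.numeric(h %*% params$W2) + as.numeric(params$b2)
  if (length(logits) != length(modality_vectors)) {
    stop("scorer must emit one logit per modality")
  }
  w <- softmax(logits)
  fused <- numeric(d)
  for (m in seq_along(modality_vectors)) {
    fused <- fused + w[m] * modality_vectors[[m]]
  }
  list(fused = fused, weights = w)
}

#' Initialize cross-attention parameters for one direction
#'
#' Multi-head attention where the query comes from one entity and key/value
#' from the other, followed by an output projection and a one-hidden-layer
#' feed-forward network (ReLU, width `model_dim`).
#'
#' @param model_dim Model width (must be divisible by `n_heads`).
#' @param n_heads Number of attention heads (8 in the reference setup).
#' @return Parameter list (`Wq`, `Wk`, `Wv`, `Wo`, `ff_W1`, `ff_b1`, `ff_W2`,
#'   `ff_b2`, `n_heads`).
#' @export
cross_attention_params <- function(model_dim, n_heads = 8L) {
  if (model_dim %% n_heads != 0L) {
    stop("model_dim must be divisible by the head count")
  }
  mk <- function() matrix(stats::rnorm(model_dim * model_dim,
                                       sd = sqrt(1 / model_dim)),
                          model_dim, model_dim)
  # the feed-forward output starts at zero so the residual fusion begins as
  # the identity and the attention branch grows in as it learns
  list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
       ff_W1 = mk(), ff_b1 = matrix(0, 1L, model_dim),
       ff_W2 = matrix(0, model_dim, model_dim),
       ff_b2 = matrix(0, 1L, model_dim),
       n_heads = n_heads)
}

#' Cross-attention between a drug and a protein representation
#'
#' Each entity is a length-1 token sequence, so the per-head softmax over the
#' single key is exactly 1 and each head returns its value projection of the
#' partner; heads are concatenated, mapped through the output projection, and
#' passed through the feed-forward network. The computation follows the
#' scaled-dot-product equations literally; with one token the query influences
#' only the (degenerate) softmax, so the output is independent of the query's
#' magnitude.
#'
#' @param query_vec Vector for the attending entity (supplies the query).
#' @param partner_vec Vector for the other entity (supplies keys and values).
#' @param params Parameters from [cross_attention_params()].
#' @return Numeric vector of length `model_dim`.
#' @export
cross_attention <- function(query_vec, partner_vec, params) {
  d <- length(query_vec)
  stopifnot(length(partner_vec) == d, nrow(params$Wq) == d)
  h <- params$n_heads
  dh <- d %/% h
  q <- as.numeric(matrix(query_vec, 1L) %*% params$Wq)
  k <- as.numeric(matrix(partner_vec, 1L) %*% params$Wk)
  v <- as.numeric(matrix(partner_vec, 1L) %*% params$Wv)
  out <- numeric(d)
  for (head in seq_len(h)) {
    sl <- ((head - 1L) * dh + 1L):(head * dh)
    score <- sum(q[sl] * k[sl]) / sqrt(dh)
    alpha <- softmax(score)  # single key: exactly 1
    out[sl] <- alpha * v[sl]
  }
  z <- as.numeric(matrix(out, 1L) %*% params$Wo)
  hdd <- pmax(as.numeric(matrix(z, 1L) %*% params$ff_W1) +
                as.numeric(params$ff_b1), 0)
  as.numeric(matrix(hdd, 1L) %*% params$ff_W2) + as.numeric(params$ff_b2)
}

#' Fuse a drug/protein pair with bidirectional cross-attention and residuals
#'
#' `z_final_D = z_soft_D + Attn(D -> T)` and
#' `z_final_T = z_soft_T + Attn(T -> D)`.
#'
#' @param z_soft_D,z_soft_T Soft-fused entity vectors at the model width.
#' @param params List with per-direction cross-attention parameters
#'   `d_to_t` and `t_to_d` (see [cross_attention_params()]).
#' @return List with `z_final_D` and `z_final_T`.
#' @export
fuse_pair <- function(z_soft_D, z_soft_T, params) {
  list(z_final_D = z_soft_D + cross_attention(z_soft_D, z_soft_T, params$d_to_t),
       z_final_T = z_soft_T + cross_attention(z_soft_T, z_soft_D, params$t_to_d))
}

#' Initialize classifier parameters
#'
#' Three linear layers (`2*model_dim -> model_dim -> model_dim/2 -> 1`) with
#' GELU activations and dropout between them, ending in a sigmoid.
#'
#' @param model_dim Entity representation width.
#' @param dropout Dropout rate used during training (ignored at evaluation).
#' @return Parameter list.
#' @export
classifier_params <- function(model_dim, dropout = 0.1) {
  d2 <- max(1L, model_dim %/% 2L)
  mk <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
  list(W1 = mk(2L * model_dim, model_dim), b1 = matrix(0, 1L, model_dim),
       W2 = mk(model_dim, d2), b2 = matrix(0, 1L, d2),
       W3 = mk(d2, 1L), b3 = matrix(0, 1L, 1L),
       dropout = dropout)
}

#' Classify a fused drug/protein pair
#'
#' Concatenates the final drug and protein vectors (drug first), applies the
#' classifier MLP in evaluation mode (dropout disabled) and returns the
#' sigmoid probability.
#'
#' @param z_final_D,z_final_T Final entity vectors from [fuse_pair()].
#' @param params Parameters from [classifier_params()].
#' @return Interaction probability in (0, 1).
#' @export
classify <- function(z_final_D, z_final_T, params) {
  x <- matrix(c(z_final_D, z_final_T), 1L)
  h1 <- gelu(x %*% params$W1 + as.numeric(params$b1))
  h2 <- gelu(h1 %*% params$W2 + as.numeric(params$b2))
  logit <- as.numeric(h2 %*% params$W3) + as.numeric(params$b3)
  stats::plogis(logit)
}

#' Composite training loss
#'
#' Mean binary cross-entropy over the batch plus `lambda` times the
#' cross-modal contrastive loss. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param y_hat Predicted probabilities.
#' @param y Binary labels.
#' @param contrastive Scalar contrastive loss for the batch.
#' @param lambda Contrastive weight (1e-4 in the reference setup).
#' @return Scalar total loss.
#' @export
total_loss <- function(y_hat, y, contrastive = 0, lambda = 1e-4) {
  stopifnot(length(y_hat) == length(y), all(y %in% c(0, 1)), lambda >= 0)
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  bce <- mean(-y * log(p) - (1 - y) * log(1 - p))
  bce + lambda * contrastive
}
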