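# Modality alignment: shared-space projection and the bidirectional
# cross-modal contrastive objective anchoring structure and relation
# embeddings to the frozen sequence modality.

#' Gaussian error linear unit
#' @param x Numeric vector or matrix.
#' @return `x * pnorm(x)` evaluated exactly.
#' @export
gelu <- function(x) x * stats::pnorm(x)

#' Initialize a modality projection
#'
#' A 2-layer feed-forward map `GELU(Z W1 + B1) W2 + B2` taking one modality's
#' embeddings into the shared projection space.
#'
#' @param input_dim Width of the modality embedding.
#' @param proj_dim Shared projection width.
#' @return List with `W1`, `B1`, `W2`, `B2`.
#' @export
projection_params <- function(input_dim, proj_dim) {
  list(W1 = matrix(stats::rnorm(input_dim * proj_dim,
                                sd = sqrt(2 / input_dim)),
                   input_dim, proj_dim),
       B1 = matrix(0, 1L, proj_dim),
       W2 = matrix(stats::rnorm(proj_dim * proj_dim, sd = sqrt(1 / proj_dim)),
                   proj_dim, proj_dim),
       B2 = matrix(0, 1L, proj_dim))
}

#' Project modality embeddings into the shared space
#'
#' @param Z Numeric matrix (entities x input dim).
#' @param params Parameters from [projection_params()].
#' @return Numeric matrix (entities x projection dim).
#' @export
project <- function(Z, params) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(params$W1)) stop("input width does not match W1")
  H <- gelu(sweep(Z %*% params$W1, 2L, -as.numeric(params$B1)))
  sweep(H %*% params$W2, 2L, -as.numeric(params$B2))
}

cosine_rows <- function(A, B, eps = 1e-8) {
  na <- sqrt(rowSums(A^2)) + eps
  nb <- sqrt(rowSums(B^2)) + eps
  (A / na) %*% t(B / nb)
}

#' Directional cross-modal contrastive loss
#'
#' For each entity i of the batch, the positive is its own representation in
#' the other modality; the negatives are the other entities within the
#' anchor's own modality. The per-batch loss is
#' `sum_i -log( exp(sim(anchor_i, other_i)/tau) /
#'              sum_j exp(sim(anchor_i, anchor_j)/tau) )`
#' with cosine similarity. The denominator deliberately runs over
#' anchor-anchor pairs (including j = i): different entities within the same
#' modality serve as negatives. A standard variant with cross-modal negatives
#' is available via `negative_mode = "cross_modality"`.
#'
#' @param Z_anchor,Z_other Row-aligned numeric matrices (batch x dim).
#' @param tau Positive temperature.
#' @param negative_mode `"same_modality"` (default) or `"cross_modality"`.
#' @return Scalar loss (sum over the batch).
#' @export
directional_contrastive_loss <- function(Z_anchor, Z_other, tau = 0.1,
                                         negative_mode = c("same_modality",
                                                           "cross_modality")) {
  negative_mode <- match.arg(negative_mode)
  Z_anchor <- as.matrix(Z_anchor); Z_other <- as.matrix(Z_other)
  stopifnot(nrow(Z_anchor) == nrow(Z_other), ncol(Z_anchor) == ncol(Z_other),
            nrow(Z_anchor) >= 1L)
  if (tau <= 0) stop("tau must be positive")
  if (any(rowSums(Z_anchor^2) == 0) || any(rowSums(Z_other^2) == 0)) {
    stop("zero-norm row")
  }
  pos <- diag(cosine_rows(Z_anchor, Z_other)) / tau
  den_sims <- if (negative_mode == "same_modality") {
    cosine_rows(Z_anchor, Z_anchor)
  } else {
    cosine_rows(Z_anchor, Z_other)
  }
  den <- den_sims / tau
  m <- apply(den, 1L, max)
  lse <- m + log(rowSums(exp(den - m)))
  sum(lse - pos)
}

#' Bidirectional contrastive loss between two modalities
#'
#' The symmetric average of the two directional losses.
#' @inheritParams directional_contrastive_loss
#' @param Z_M1,Z_M2 Row-aligned projected modality matrices.
#' @return Scalar loss.
#' @export
bidirectional_loss <- function(Z_M1, Z_M2, tau = 0.1,
                               negative_mode = "same_modality") {
  0.5 * (directional_contrastive_loss(Z_M1, Z_M2, tau, negative_mode) +
         directional_contrastive_loss(Z_M2, Z_M1, tau, negative_mode))
}

#' Total cross-modal contrastive loss over both entity classes
#'
#' Sums four bidirectional terms, anchoring the structural and relational
#' modalities to the sequence modality separately for drugs and targets:
#' (seq_D, struct_D), (seq_D, rel_D), (seq_T, struct_T), (seq_T, rel_T).
#' Structure and relation are never aligned to each other directly.
#'
#' @param drug Named list of projected drug matrices: `sequence`, `structure`,
#'   `relation` (row-aligned by drug).
#' @param target Same for targets.
#' @param tau Temperature.
#' @param negative_mode See [directional_contrastive_loss()].
#' @return Scalar loss.
#' @export
total_contrastive_loss <- function(drug, target, tau = 0.1,
                                   negative_mode = "same_modality") {
  pairs <- list(list(drug$sequence, drug$structure),
                list(drug$sequence, drug$relation),
                list(target$sequence, target$structure),
                list(target$sequence, target$relation))
  total <- 0
  for (p in pairs) {
    if (is.null(p[[1L]]) || is.null(p[[2L]])) next  # ablated modality
    total <- total + bidirectional_loss(p[[1L]], p[[2L]], tau, negative_mode)
  }
  total
}
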