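# Structural encoders: a 2-layer graph isomorphism network (GIN) over
# molecular graphs and a multi-scale CNN over tokenized protein sequences.

#' Initialize GIN parameters
#'
#' Two layers; each layer's MLP is linear-ReLU-linear (widths
#' `input_dim -> hidden_dim -> hidden_dim` for layer 1, then
#' `hidden_dim -> hidden_dim -> hidden_dim`), with a learnable scalar epsilon
#' per layer (initialized at 0).
#'
#' @param input_dim Atom feature width (79).
#' @param hidden_dim Output width of both layers.
#' @return List of two per-layer lists (`eps`, `W1`, `b1`, `W2`, `b2`).
#' @export
gin_params <- function(input_dim = 79L, hidden_dim = 128L) {
  mk <- function(d_in, d_out) {
    sd1 <- sqrt(2 / d_in)
    sd2 <- sqrt(2 / d_out)
    list(eps = 0,
         W1 = matrix(stats::rnorm(d_in * d_out, sd = sd1), d_in, d_out),
         b1 = matrix(0, 1L, d_out),
         W2 = matrix(stats::rnorm(d_out * d_out, sd = sd2), d_out, d_out),
         b2 = matrix(0, 1L, d_out))
  }
  list(mk(input_dim, hidden_dim), mk(hidden_dim, hidden_dim))
}

# Neighbor-sum matrix (dense) for a small undirected bond list.
adjacency_from_bonds <- function(bonds, n) {
  A <- matrix(0, n, n)
  if (NROW(bonds) > 0L) {
    for (r in seq_len(NROW(bonds))) {
      i <- bonds[r, 1L]; j <- bonds[r, 2L]
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  A
}

#' One GIN layer
#'
#' Computes `MLP((1 + eps) * h_i + sum_{j in N(i)} h_j)` for every node.
#' Isolated nodes use an empty (zero) neighbor sum.
#'
#' @param node_states Numeric matrix (nodes x dim).
#' @param bonds Two-column matrix of undirected edges (1-based indices).
#' @param eps Scalar self-weight.
#' @param mlp Function mapping the aggregated state matrix to the layer
#'   output (any callable respecting the input width).
#' @return The transformed node-state matrix.
#' @export
gin_layer <- function(node_states, bonds, eps, mlp) {
  H <- as.matrix(node_states)
  n <- nrow(H)
  A <- adjacency_from_bonds(bonds, n)
  agg <- (1 + eps) * H + A %*% H
  out <- mlp(agg)
  if (NROW(out) != n) stop("mlp changed the node count")
  out
}

gin_mlp <- function(layer) {
  function(x) {
    h <- pmax(sweep(x %*% layer$W1, 2L, -as.numeric(layer$b1)), 0)
    sweep(h %*% layer$W2, 2L, -as.numeric(layer$b2))
  }
}

#' Encode a drug's molecular graph into a structure embedding
#'
#' Two stacked GIN layers followed by a mean over the atoms of the final
#' layer's states (the readout producing one vector per molecule).
#'
#' @param graph A `molecular_graph` from [parse_smiles_to_graph()].
#' @param params Parameters from [gin_params()].
#' @return Numeric vector (hidden dim).
#' @export
encode_drug_structure <- function(graph, params) {
  stopifnot(inherits(graph, "molecular_graph"))
  H <- graph$atom_features
  if (nrow(H) < 1L) stop("empty molecular graph")
  for (layer in params) {
    H <- gin_layer(H, graph$bonds, layer$eps, gin_mlp(layer))
  }
  colMeans(H)
}

#' Initialize multi-scale protein CNN parameters
#'
#' A learnable token-embedding table and three parallel branches with kernel
#' sizes 1, 3 and 5; each branch stacks three convolution layers (ReLU,
#' `hidden_dim` channels throughout, length-preserving zero padding). Branch
#' outputs are globally max-pooled over positions, concatenated, and linearly
#' mapped to `hidden_dim`.
#'
#' @param vocab_size Token vocabulary size excluding the padding index.
#' @param emb_dim Token embedding width (defaults to `hidden_dim`).
#' @param hidden_dim Output width.
#' @return Parameter list (`emb`, `branches` with per-layer `W`/`b`, `W_out`,
#'   `b_out`, `kernel_sizes`).
#' @export
protein_cnn_params <- function(vocab_size = 21L, emb_dim = NULL,
                               hidden_dim = 128L) {
  if (is.null(emb_dim)) emb_dim <- hidden_dim
  ks <- c(1L, 3L, 5L)
  branches <- lapply(ks, function(k) {
    lapply(1:3, function(l) {
      d_in <- if (l == 1L) emb_dim else hidden_dim
      sd <- sqrt(2 / (d_in * k))
      list(W = matrix(stats::rnorm(d_in * k * hidden_dim, sd = sd),
                      d_in * k, hidden_dim),
           b = matrix(0, 1L, hidden_dim))
    })
  })
  list(emb = matrix(stats::rnorm(vocab_size * emb_dim, sd = 0.1),
                    vocab_size, emb_dim),
       branches = branches,
       kernel_sizes = ks,
       W_out = matrix(stats::rnorm(3L * hidden_dim * hidden_dim,
                                   sd = sqrt(2 / (3 * hidden_dim))),
                      3L * hidden_dim, hidden_dim),
       b_out = matrix(0, 1L, hidden_dim),
       emb_dim = emb_dim, hidden_dim = hidden_dim)
}

# im2col row-gather indices for a length-L sequence and kernel size k;
# out-of-range positions map to `zero_row` (index of an all-zero row).
im2col_indices <- function(L, k, zero_row, offset = 0L) {
  half <- (k - 1L) %/% 2L
  idx <- matrix(0L, L, k)
  for (d in seq_len(k)) {
    pos <- seq_len(L) + (d - 1L - half)
    pos[pos < 1L | pos > L] <- NA_integer_
    idx[, d] <- ifelse(is.na(pos), zero_row, pos + offset)
  }
  idx
}

conv1d_same <- function(X, W, b, k) {
  # X: L x C_in; W: (C_in*k) x C_out. Zero padding at the boundaries.
  L <- nrow(X)
  Xz <- rbind(X, 0)
  idx <- im2col_indices(L, k, zero_row = L + 1L)
  cols <- do.call(cbind, lapply(seq_len(k), function(d) Xz[idx[, d], , drop = FALSE]))
  sweep(cols %*% W, 2L, -as.numeric(b))
}

#' Encode a tokenized protein into a structure embedding
#'
#' Embeds the tokens, runs the three convolution branches, max-pools each
#' branch over sequence positions (adaptive global pooling, so the output
#' width never depends on sequence length), concatenates the branch outputs
#' and maps them to the output width. Trailing padding (token index 0) is
#' removed before the convolutions, so padding never influences the result.
#'
#' @param tokens Integer token vector from [tokenize_protein()] (padding 0).
#' @param params Parameters from [protein_cnn_params()].
#' @return Numeric vector (hidden dim).
#' @export
encode_protein_structure <- function(tokens, params) {
  tokens <- as.integer(tokens)
  nz <- which(tokens != 0L)
  if (length(nz) == 0L) stop("all-padding protein input")
  tokens <- tokens[seq_len(max(nz))]
  if (any(tokens == 0L)) tokens <- tokens[tokens != 0L]
  X0 <- params$emb[tokens, , drop = FALSE]
  pooled <- vector("list", length(params$kernel_sizes))
  for (bidx in seq_along(params$kernel_sizes)) {
    k <- params$kernel_sizes[bidx]
    X <- X0
    for (layer in params$branches[[bidx]]) {
      X <- pmax(conv1d_same(X, layer$W, layer$b, k), 0)
    }
    pooled[[bidx]] <- apply(X, 2L, max)
  }
  as.numeric(unlist(pooled) %*% params$W_out) + as.numeric(params$b_out)
}
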