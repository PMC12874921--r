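# Relational modality: entity relation networks (drug-drug cosine similarity,
# protein-protein interaction), top-k sparsification, 2-hop subgraph
# extraction, and the GATv2 subgraph encoder.

#' Construct a relational network
#'
#' @param node_ids Ordered character vector of node identifiers.
#' @param edges Data frame/matrix with columns `i`, `j` (1-based node indices)
#'   and `weight`; stored undirected with `i < j`, self-edges forbidden.
#' @param node_features Numeric matrix of per-node features (typically the
#'   frozen sequence embeddings), rows aligned with `node_ids`.
#' @return An object of class `relational_network`.
#' @export
relational_network <- function(node_ids, edges, node_features) {
  node_features <- as.matrix(node_features)
  stopifnot(length(node_ids) == nrow(node_features))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    stopifnot(all(c("i", "j", "weight") %in% names(edges)))
    lo <- pmin(edges$i, edges$j); hi <- pmax(edges$i, edges$j)
    stopifnot(all(lo >= 1L), all(hi <= length(node_ids)), all(lo != hi),
              all(is.finite(edges$weight)))
    edges <- data.frame(i = lo, j = hi, weight = edges$weight)
    edges <- edges[!duplicated(paste(edges$i, edges$j)), , drop = FALSE]
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  }
  structure(list(node_ids = as.character(node_ids), edges = edges,
                 node_features = node_features),
            class = "relational_network")
}

#' Build a complete cosine-similarity network over entities
#'
#' Edge weight between two entities is the cosine similarity of their
#' embedding rows; self-edges are excluded. Used for the drug-drug similarity
#' network built on frozen sequence embeddings.
#'
#' @param embeddings An [embedding_matrix()] with at least two entities.
#' @return A `relational_network` on the same entities.
#' @export
cosine_similarity_network <- function(embeddings) {
  stopifnot(inherits(embeddings, "embedding_matrix"))
  X <- embeddings$vectors
  if (nrow(X) < 2L) stop("need at least 2 entities")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    stop("zero-norm embedding row for entity: ",
         embeddings$entity_ids[which(nrm == 0)[1L]])
  }
  Xn <- X / nrm
  S <- Xn %*% t(Xn)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], weight = S[idx])
  relational_network(embeddings$entity_ids, edges, X)
}

#' Build a relational network from a PPI edge list
#'
#' @param ppi_edges Data frame from [load_ppi_edges()] (columns a, b, score).
#' @param embeddings An [embedding_matrix()] providing node order and features;
#'   edges whose endpoints are not among its entities are dropped.
#' @param score_scale Scores are divided by this value (1000, the STRING
#'   convention) to give weights on a 0-1 scale.
#' @return A `relational_network`.
#' @export
ppi_network <- function(ppi_edges, embeddings, score_scale = 1000) {
  stopifnot(inherits(embeddings, "embedding_matrix"))
  ids <- embeddings$entity_ids
  keep <- ppi_edges$a %in% ids & ppi_edges$b %in% ids
  pe <- ppi_edges[keep, , drop = FALSE]
  edges <- data.frame(i = match(pe$a, ids), j = match(pe$b, ids),
                      weight = pe$score / score_scale)
  relational_network(ids, edges, embeddings$vectors)
}

#' Per-node top-k sparsification
#'
#' Every node keeps its k highest-weight incident edges (ties broken toward
#' the lower partner index); the surviving edge set is the union over nodes,
#' so an edge remains if either endpoint selected it. Per-node selection keeps
#' all entities connected to their strongest neighbors, which a global top-k
#' cut does not guarantee.
#'
#' @param network A `relational_network`.
#' @param k Number of edges kept per node (>= 1).
#' @return A sparsified `relational_network`.
#' @export
topk_sparsify <- function(network, k) {
  stopifnot(inherits(network, "relational_network"))
  if (k < 1L) stop("k must be >= 1")
  e <- network$edges
  if (nrow(e) == 0L) return(network)
  n <- length(network$node_ids)
  # incident edges per node, both orientations
  inc_node <- c(e$i, e$j)
  partner <- c(e$j, e$i)
  eid <- rep(seq_len(nrow(e)), 2L)
  w <- rep(e$weight, 2L)
  keep <- logical(nrow(e))
  for (v in unique(inc_node)) {
    sel <- which(inc_node == v)
    ord <- sel[order(-w[sel], partner[sel])]
    keep[eid[ord[seq_len(min(k, length(ord)))]]] <- TRUE
  }
  relational_network(network$node_ids, e[keep, , drop = FALSE],
                     network$node_features)
}

#' Extract the 2-hop subgraph around a center node
#'
#' Members are the nodes reachable from the center within two hops of the
#' (sparsified) network. When the member count exceeds `cap`, the center is
#' kept, then 1-hop neighbors by descending edge weight, then 2-hop nodes by
#' descending best 2-hop path weight (minimum of the two hops), with index
#' tie-breaks. Induced edges are the network edges restricted to members.
#'
#' @param network A `relational_network` (typically after [topk_sparsify()]).
#' @param center Node index (1-based) or node id.
#' @param cap Maximum member count (default 64).
#' @return An object of class `relational_subgraph`: list with `center`
#'   (index), `members` (sorted index vector), `induced_edges` (data frame
#'   i/j/weight in subgraph-local indices), `member_ids`.
#' @export
extract_2hop_subgraph <- function(network, center, cap = 64L) {
  stopifnot(inherits(network, "relational_network"), cap >= 1L)
  if (is.character(center)) center <- match(center, network$node_ids)
  n <- length(network$node_ids)
  if (is.na(center) || center < 1L || center > n) {
    stop("center is not a node of the network")
  }
  e <- network$edges
  nbr <- function(v) {
    rows <- which(e$i == v | e$j == v)
    data.frame(node = ifelse(e$i[rows] == v, e$j[rows], e$i[rows]),
               weight = e$weight[rows])
  }
  h1 <- nbr(center)
  h1 <- h1[order(-h1$weight, h1$node), , drop = FALSE]
  h2_nodes <- integer(0); h2_best <- numeric(0)
  for (r in seq_len(nrow(h1))) {
    nb <- nbr(h1$node[r])
    pathw <- pmin(h1$weight[r], nb$weight)  # bottleneck weight of the 2-hop path
    for (q in seq_len(nrow(nb))) {
      v <- nb$node[q]
      pos <- match(v, h2_nodes)
      if (is.na(pos)) {
        h2_nodes <- c(h2_nodes, v); h2_best <- c(h2_best, pathw[q])
      } else if (pathw[q] > h2_best[pos]) {
        h2_best[pos] <- pathw[q]
      }
    }
  }
  drop2 <- h2_nodes %in% c(center, h1$node)
  h2_nodes <- h2_nodes[!drop2]; h2_best <- h2_best[!drop2]
  ord2 <- order(-h2_best, h2_nodes)
  ranked <- c(center, h1$node, h2_nodes[ord2])
  members <- ranked[seq_len(min(cap, length(ranked)))]
  members <- sort(unique(members))
  sel <- e$i %in% members & e$j %in% members
  ind <- e[sel, , drop = FALSE]
  ind$i <- match(ind$i, members)
  ind$j <- match(ind$j, members)
  rownames(ind) <- NULL
  structure(list(center = center,
                 center_local = match(center, members),
                 members = members,
                 member_ids = network$node_ids[members],
                 induced_edges = ind),
            class = "relational_subgraph")
}

#' Initialize GATv2 parameters
#'
#' Two layers, each with a weight matrix over the concatenated endpoint states
#' (left/right blocks `W_l`, `W_r`) and an attention vector `a`. Attention
#' logits use LeakyReLU(0.2) (the GATv2 convention); layer outputs use ELU.
#'
#' @param input_dim Width of the node features entering layer 1.
#' @param hidden_dim Output width of both layers.
#' @param init_sd Standard deviation of the Gaussian initialization.
#' @return List of per-layer parameter lists (`Wl`, `Wr`, `a`).
#' @export
gatv2_params <- function(input_dim, hidden_dim, init_sd = NULL) {
  mk <- function(d_in, d_out) {
    sd <- if (is.null(init_sd)) sqrt(2 / d_in) else init_sd
    list(Wl = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
         Wr = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
         a = matrix(stats::rnorm(d_out, sd = sd), d_out, 1L))
  }
  list(mk(input_dim, hidden_dim), mk(hidden_dim, hidden_dim))
}

leaky_relu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# Directed edge list (src = attending node i, dst = neighbor j) from an
# induced undirected edge set, with self-loops added for isolated nodes so
# every neighborhood is non-empty.
gat_directed_edges <- function(induced_edges, n_nodes) {
  src <- c(induced_edges$i, induced_edges$j)
  dst <- c(induced_edges$j, induced_edges$i)
  deg <- tabulate(src, nbins = n_nodes)
  iso <- which(deg == 0L)
  list(src = c(src, iso), dst = c(dst, iso))
}

#' One GATv2 layer over a subgraph
#'
#' Attention logits are `a' LeakyReLU(W_l h_i + W_r h_j)`, softmax-normalized
#' over each node's neighbors; the node update is
#' `ELU(sum_j alpha_ij W_r h_j)`. Isolated nodes receive a self-loop so the
#' neighbor sum is non-empty.
#'
#' @param node_states Numeric matrix (nodes x input dim).
#' @param induced_edges Data frame with 1-based local indices `i`, `j`
#'   (undirected; both directions are used).
#' @param params One layer's parameter list (`Wl`, `Wr`, `a`), e.g. one
#'   element of [gatv2_params()].
#' @param return_attention If TRUE, also return the per-edge attention
#'   weights (with `src`/`dst` indices).
#' @return Updated node-state matrix, or a list `(states, attention)` when
#'   `return_attention = TRUE`.
#' @export
gatv2_layer <- function(node_states, induced_edges, params,
                        return_attention = FALSE) {
  H <- as.matrix(node_states)
  n <- nrow(H)
  if (ncol(H) != nrow(params$Wl)) stop("node state width does not match Wl")
  de <- gat_directed_edges(induced_edges, n)
  src <- de$src; dst <- de$dst
  Hl <- H %*% params$Wl
  Hr <- H %*% params$Wr
  logits <- as.numeric(leaky_relu(Hl[src, , drop = FALSE] +
                                  Hr[dst, , drop = FALSE]) %*% params$a)
  # numerically stable per-source softmax
  mx <- tapply(logits, src, max)
  ex <- exp(logits - as.numeric(mx[as.character(src)]))
  den <- tapply(ex, src, sum)
  alpha <- ex / as.numeric(den[as.character(src)])
  msg <- Hr[dst, , drop = FALSE] * alpha
  out <- rowsum(msg, group = src)
  states <- matrix(0, n, ncol(Hr))
  states[as.integer(rownames(out)), ] <- out
  states <- elu(states)
  if (return_attention) {
    list(states = states,
         attention = data.frame(src = src, dst = dst, alpha = alpha))
  } else {
    states
  }
}

#' Encode an entity through its relational subgraph
#'
#' Two GATv2 layers over the subgraph followed by a mean over all member
#' nodes' final states.
#'
#' @param subgraph A `relational_subgraph` from [extract_2hop_subgraph()].
#' @param node_features Matrix of features for the full network's nodes (rows
#'   indexed by global node index), typically the frozen sequence embeddings.
#' @param params Parameters from [gatv2_params()].
#' @return Numeric vector (hidden dim).
#' @export
encode_relation <- function(subgraph, node_features, params) {
  stopifnot(inherits(subgraph, "relational_subgraph"))
  H <- as.matrix(node_features)[subgraph$members, , drop = FALSE]
  if (nrow(H) == 0L) stop("empty subgraph")
  h1 <- gatv2_layer(H, subgraph$induced_edges, params[[1L]])
  h2 <- gatv2_layer(h1, subgraph$induced_edges, params[[2L]])
  colMeans(h2)
}

#' Serialize / restore a relational network
#'
#' Writes the edge list as a three-column TSV (node ids and weight) and the
#' node order as a plain ids file, so sparsified networks can be audited and
#' reloaded exactly.
#'
#' @param network A `relational_network`.
#' @param edges_path,ids_path Output file paths.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(network, edges_path, ids_path) {
  stopifnot(inherits(network, "relational_network"))
  e <- network$edges
  utils::write.table(
    data.frame(a = network$node_ids[e$i], b = network$node_ids[e$j],
               weight = e$weight),
    edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(network$node_ids, ids_path)
  invisible(edges_path)
}

#' @param node_features Feature matrix for the restored network's nodes
#'   (rows in ids-file order).
#' @rdname write_network
#' @export
read_network <- function(edges_path, ids_path, node_features) {
  ids <- readLines(ids_path, warn = FALSE)
  df <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  relational_network(ids,
                     data.frame(i = match(df$a, ids), j = match(df$b, ids),
                                weight = df$weight),
                     node_features)
}
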