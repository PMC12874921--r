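# Full tri-modal model: configuration, parameter initialization, entity
# feature caching, and the training/evaluation forward pass expressed on the
# autodiff tape.

#' Model and training configuration
#'
#' Defaults follow the reference setup: AdamW with learning rate 5e-4, batch
#' size 16, dropout 0.1, up to 100 epochs, contrastive temperature 0.1 and
#' weight 1e-4, 8 cross-attention heads, and 128-wide hidden/projection
#' dimensions. Scaled-down experiments override the widths and epoch budget.
#'
#' @param gin_dim Drug GIN output width.
#' @param cnn_dim Protein CNN output width (token embedding width matches).
#' @param gat_dim GATv2 hidden width (both entity classes).
#' @param proj_dim Shared projection width; also the fusion model width.
#' @param soft_hidden Soft-attention scorer hidden width.
#' @param cross_heads Cross-attention head count (`proj_dim` must divide).
#' @param tau Contrastive temperature (> 0).
#' @param lambda Contrastive loss weight (>= 0).
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW weight decay (applied to weight matrices).
#' @param batch_size Training batch size (>= 2; the contrastive term needs
#'   in-batch negatives).
#' @param dropout Classifier dropout rate.
#' @param max_epochs Epoch cap; the checkpoint with the best validation AUROC
#'   is returned.
#' @param top_k Per-node top-k for relation-network sparsification.
#' @param subgraph_cap Maximum members of a 2-hop subgraph.
#' @param negative_mode Contrastive negatives: `"same_modality"` (as
#'   formulated) or `"cross_modality"` (the standard variant).
#' @param modalities Subset of `c("structure", "sequence", "relation")`.
#' @param use_contrastive,use_soft_attention,use_cross_attention Module
#'   switches for ablations.
#' @param threshold Decision threshold for F1/accuracy.
#' @param protein_max_len Protein token cap.
#' @param smiles_max_len SMILES length cap for provider truncation.
#' @param seed Master seed: fully determines initialization, batch order and
#'   dropout.
#' @return A list of class `dti_config`.
#' @export
dti_config <- function(gin_dim = 128L, cnn_dim = 128L, gat_dim = 128L,
                       proj_dim = 128L, soft_hidden = 128L, cross_heads = 8L,
                       tau = 0.1, lambda = 1e-4,
                       lr = 5e-4, weight_decay = 0.01, batch_size = 16L,
                       dropout = 0.1, max_epochs = 100L,
                       top_k = 5L, subgraph_cap = 64L,
                       negative_mode = c("same_modality", "cross_modality"),
                       modalities = c("structure", "sequence", "relation"),
                       use_contrastive = TRUE, use_soft_attention = TRUE,
                       use_cross_attention = TRUE,
                       threshold = 0.5, protein_max_len = 1024L,
                       smiles_max_len = 510L, seed = 1L) {
  negative_mode <- match.arg(negative_mode)
  modalities <- match.arg(modalities, several.ok = TRUE)
  stopifnot(length(modalities) >= 1L, tau > 0, lambda >= 0, lr > 0,
            batch_size >= 2L)
  if (use_cross_attention && proj_dim %% cross_heads != 0L) {
    stop("proj_dim must be divisible by cross_heads")
  }
  structure(as.list(environment()), class = "dti_config")
}

# ---- parameter container ---------------------------------------------------

#' Initialize all trainable parameters
#'
#' @param config A [dti_config()].
#' @param drug_seq_dim,prot_seq_dim Widths of the frozen sequence embeddings.
#' @return Nested parameter list of class `dti_params`.
#' @export
dti_params_init <- function(config, drug_seq_dim, prot_seq_dim) {
  with_seed(config$seed * 7L + 13L, {
    m <- config$modalities
    p <- list()
    if ("structure" %in% m) {
      p$gin <- gin_params(79L, config$gin_dim)
      p$cnn <- protein_cnn_params(vocab_size = length(protein_vocab()),
                                  emb_dim = config$cnn_dim,
                                  hidden_dim = config$cnn_dim)
    }
    if ("relation" %in% m) {
      p$gat_drug <- gatv2_params(drug_seq_dim, config$gat_dim)
      p$gat_prot <- gatv2_params(prot_seq_dim, config$gat_dim)
    }
    in_dim <- list(drug = list(structure = config$gin_dim,
                               sequence = drug_seq_dim,
                               relation = config$gat_dim),
                   target = list(structure = config$cnn_dim,
                                 sequence = prot_seq_dim,
                                 relation = config$gat_dim))
    p$proj <- list()
    for (cls in c("drug", "target")) {
      p$proj[[cls]] <- list()
      for (mod in m) {
        p$proj[[cls]][[mod]] <- projection_params(in_dim[[cls]][[mod]],
                                                  config$proj_dim)
      }
    }
    if (config$use_soft_attention && length(m) > 1L) {
      p$soft <- list(drug = soft_attention_params(config$proj_dim,
                                                  config$soft_hidden,
                                                  length(m)),
                     target = soft_attention_params(config$proj_dim,
                                                    config$soft_hidden,
                                                    length(m)))
    }
    if (config$use_cross_attention) {
      p$cross <- list(d_to_t = cross_attention_params(config$proj_dim,
                                                      config$cross_heads),
                      t_to_d = cross_attention_params(config$proj_dim,
                                                      config$cross_heads))
    }
    p$clf <- classifier_params(config$proj_dim, config$dropout)
    class(p) <- "dti_params"
    p
  })
}

# Flatten a nested parameter list into a named list of numeric matrices.
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    if (nm %in% c("kernel_sizes", "n_heads", "dropout", "emb_dim",
                  "hidden_dim")) next  # structural metadata, not trainable
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(v)) {
      nms <- names(v)
      if (is.null(nms)) names(v) <- paste0("l", seq_along(v))
      out <- c(out, flatten_params(v, key))
    } else if (is.numeric(v)) {
      out[[key]] <- as_mat(v)
    }
  }
  out
}

# Write flat values back into the nested skeleton.
unflatten_params <- function(flat, skeleton) {
  assign_path <- function(x, path, value) {
    if (length(path) == 1L) {
      orig <- x[[path]]
      x[[path]] <- if (is.matrix(orig)) value else as.numeric(value)
      return(x)
    }
    x[[path[1L]]] <- assign_path(x[[path[1L]]], path[-1L], value)
    x
  }
  # reproduce the same implicit list names used when flattening
  name_lists <- function(x) {
    if (!is.list(x)) return(x)
    nms <- names(x)
    if (is.null(nms)) names(x) <- paste0("l", seq_along(x))
    for (nm in names(x)) x[[nm]] <- name_lists(x[[nm]])
    x
  }
  restore <- function(x) {
    if (!is.list(x)) return(x)
    nms <- names(x)
    if (all(grepl("^l[0-9]+$", nms))) names(x) <- NULL
    for (i in seq_along(x)) x[[i]] <- restore(x[[i]])
    x
  }
  sk <- name_lists(skeleton)
  for (key in names(flat)) {
    sk <- assign_path(sk, strsplit(key, ".", fixed = TRUE)[[1L]], flat[[key]])
  }
  out <- restore(sk)
  class(out) <- class(skeleton)
  out
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(flat, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(flat)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    step <- (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    decay <- if (nrow(flat[[key]]) > 1L) weight_decay * flat[[key]] else 0
    flat[[key]] <- flat[[key]] - lr * (step + decay)
  }
  list(flat = flat, state = state)
}

# ---- entity feature cache --------------------------------------------------

#' Precompute frozen per-entity inputs for training and evaluation
#'
#' Parses every drug's molecular graph, tokenizes every protein, attaches the
#' frozen sequence-embedding matrices, builds the sparsified relation networks
#' (drug-drug cosine similarity; protein PPI when edges are supplied,
#' otherwise protein-protein cosine similarity) and extracts each entity's
#' 2-hop subgraph. Everything here is label-free, so no information leaks
#' across evaluation splits; the relation networks are transductive over the
#' entity sets.
#'
#' @param dataset An `interaction_dataset`.
#' @param drug_embeddings,protein_embeddings [embedding_matrix()] objects
#'   covering the dataset's entities.
#' @param config A [dti_config()].
#' @param ppi_edges Optional PPI edge data frame (columns a/b/score).
#' @return A list of class `dti_cache`.
#' @export
build_entity_cache <- function(dataset, drug_embeddings, protein_embeddings,
                               config = dti_config(), ppi_edges = NULL) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  drug_ids <- names(dataset$drug_table)
  prot_ids <- names(dataset$protein_table)
  stopifnot(all(drug_ids %in% drug_embeddings$entity_ids),
            all(prot_ids %in% protein_embeddings$entity_ids))
  dseq <- drug_embeddings$vectors[match(drug_ids, drug_embeddings$entity_ids),
                                  , drop = FALSE]
  pseq <- protein_embeddings$vectors[match(prot_ids,
                                           protein_embeddings$entity_ids),
                                     , drop = FALSE]

  graphs <- NULL; tokens <- NULL
  if ("structure" %in% config$modalities) {
    graphs <- lapply(dataset$drug_table, parse_smiles_to_graph)
    tokens <- lapply(dataset$protein_table, function(s) {
      tk <- tokenize_protein(s, max_len = config$protein_max_len)
      tk[tk != 0L]
    })
  }

  dsub <- NULL; psub <- NULL
  if ("relation" %in% config$modalities) {
    dnet <- topk_sparsify(
      cosine_similarity_network(embedding_matrix(drug_ids, dseq, "sequence")),
      config$top_k)
    pemb <- embedding_matrix(prot_ids, pseq, "sequence")
    pnet0 <- if (!is.null(ppi_edges) && nrow(ppi_edges) > 0L) {
      ppi_network(ppi_edges, pemb)
    } else {
      cosine_similarity_network(pemb)
    }
    pnet <- topk_sparsify(pnet0, config$top_k)
    subg <- function(net, i) {
      sg <- extract_2hop_subgraph(net, i, cap = config$subgraph_cap)
      de <- gat_directed_edges(sg$induced_edges, length(sg$members))
      list(members = sg$members, src = de$src, dst = de$dst,
           n = length(sg$members))
    }
    dsub <- lapply(seq_along(drug_ids), function(i) subg(dnet, i))
    psub <- lapply(seq_along(prot_ids), function(i) subg(pnet, i))
  }

  structure(list(drug_ids = drug_ids, prot_ids = prot_ids,
                 graphs = graphs, tokens = tokens,
                 drug_seq = dseq, prot_seq = pseq,
                 drug_sub = dsub, prot_sub = psub),
            class = "dti_cache")
}

# ---- forward-pass building blocks (autodiff) -------------------------------

ad_linear <- function(tape, x, W, b, act = "identity") {
  ad_dense(tape, x, W, b, act)
}

# batched GIN over the disjoint union of the batch's molecular graphs
forward_drug_structure <- function(tape, pn, cache, du) {
  graphs <- cache$graphs[du]
  natoms <- vapply(graphs, function(g) nrow(g$atom_features), 1L)
  offs <- cumsum(c(0L, natoms[-length(natoms)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  N <- nrow(X)
  tri <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    b <- graphs[[i]]$bonds
    if (NROW(b) == 0L) return(NULL)
    rbind(cbind(b[, 1L] + offs[i], b[, 2L] + offs[i]),
          cbind(b[, 2L] + offs[i], b[, 1L] + offs[i]))
  }))
  if (is.null(tri)) tri <- matrix(integer(0), ncol = 2L)
  atom_graph <- rep(seq_along(graphs), natoms)
  h <- ad_const(tape, X)
  for (layer in pn$gin) {
    self <- ad_scale_by(tape, h, ad_addc(tape, layer$eps, 1))
    agg <- if (nrow(tri) > 0L) {
      ad_add(tape, self, ad_neighbor_sum(tape, h, tri[, 1L], tri[, 2L], N))
    } else {
      self
    }
    h <- ad_linear(tape,
                   ad_linear(tape, agg, layer$W1, layer$b1, act = "relu"),
                   layer$W2, layer$b2)
  }
  ad_group_mean(tape, h, atom_graph, length(graphs))
}

# batched multi-scale CNN over the batch's (ragged) protein sequences
forward_protein_structure <- function(tape, pn, cache, pu) {
  toks <- cache$tokens[pu]
  L <- vapply(toks, length, 1L)
  starts <- cumsum(c(0L, L[-length(L)]))
  N <- sum(L)
  prot_of <- rep(seq_along(L), L)
  local <- unlist(lapply(L, seq_len))
  E <- ad_rows(tape, pn$cnn$emb, unlist(toks))
  pooled <- vector("list", length(pn$cnn$kernel_sizes))
  for (bidx in seq_along(pn$cnn$kernel_sizes)) {
    k <- pn$cnn$kernel_sizes[bidx]
    half <- (k - 1L) %/% 2L
    idx <- matrix(0L, N, k)
    for (d in seq_len(k)) {
      lp <- local + (d - 1L - half)
      col <- starts[prot_of] + lp
      col[lp < 1L | lp > L[prot_of]] <- 0L   # zero padding
      idx[, d] <- col
    }
    h <- E
    for (layer in pn$cnn$branches[[bidx]]) {
      h <- ad_linear(tape, ad_im2col(tape, h, idx), layer$W, layer$b,
                     act = "relu")
    }
    pooled[[bidx]] <- ad_rowmax_by(tape, h, prot_of, length(pu))
  }
  ad_linear(tape, ad_cbind(tape, pooled), pn$cnn$W_out, pn$cnn$b_out)
}

ad_gatv2_layer <- function(tape, H, src, dst, n, layer) {
  Hl <- ad_matmul(tape, H, layer$Wl)
  Hr <- ad_matmul(tape, H, layer$Wr)
  s <- ad_matmul(tape,
                 ad_leaky_relu(tape, ad_add(tape,
                                            ad_rows(tape, Hl, src),
                                            ad_rows(tape, Hr, dst))),
                 layer$a)
  sv <- as.numeric(ad_value(s))
  m_edge <- dti_segment_max_vec(sv, as.integer(src), max(src))[src]
  e <- ad_exp(tape, ad_sub_rowconst(tape, s, matrix(m_edge, ncol = 1L)))
  den <- ad_rowsum_by(tape, e, src, n)
  alpha <- ad_mul(tape, e, ad_rows(tape, ad_recip(tape, den), src))
  ad_elu(tape, ad_edge_aggregate(tape, Hr, alpha, src, dst, n))
}

# batched GATv2 over the union of the batch entities' 2-hop subgraphs
forward_relation <- function(tape, gat, subs, seq_mat, ent_idx) {
  sel <- subs[ent_idx]
  sizes <- vapply(sel, function(s) s$n, 1L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  members <- unlist(lapply(sel, function(s) s$members))
  src <- unlist(lapply(seq_along(sel), function(i) sel[[i]]$src + offs[i]))
  dst <- unlist(lapply(seq_along(sel), function(i) sel[[i]]$dst + offs[i]))
  N <- sum(sizes)
  H <- ad_const(tape, seq_mat[members, , drop = FALSE])
  h1 <- ad_gatv2_layer(tape, H, src, dst, N, gat[[1L]])
  h2 <- ad_gatv2_layer(tape, h1, src, dst, N, gat[[2L]])
  ad_group_mean(tape, h2, rep(seq_along(sel), sizes), length(sel))
}

ad_project <- function(tape, Z, pp) {
  ad_linear(tape, ad_linear(tape, Z, pp$W1, pp$B1, act = "gelu"),
            pp$W2, pp$B2)
}

ad_directional_contrastive <- function(tape, Za, Zo, tau, negative_mode) {
  Zan <- ad_rownorm(tape, Za)
  Zon <- ad_rownorm(tape, Zo)
  pos <- ad_mulc(tape, ad_rowsums(tape, ad_mul(tape, Zan, Zon)), 1 / tau)
  other <- if (negative_mode == "same_modality") Zan else Zon
  A <- ad_mulc(tape, ad_matmul(tape, Zan, ad_t(tape, other)), 1 / tau)
  m <- apply(ad_value(A), 1L, max)
  lse0 <- ad_log(tape, ad_rowsums(tape, ad_exp(tape,
            ad_sub_rowconst(tape, A, matrix(m, nrow(ad_value(A)),
                                            ncol(ad_value(A)))))))
  lse <- ad_add(tape, lse0, matrix(m, ncol = 1L))
  ad_sum(tape, ad_sub(tape, lse, pos))
}

ad_bidirectional <- function(tape, Z1, Z2, tau, negative_mode) {
  ad_mulc(tape,
          ad_add(tape,
                 ad_directional_contrastive(tape, Z1, Z2, tau, negative_mode),
                 ad_directional_contrastive(tape, Z2, Z1, tau, negative_mode)),
          0.5)
}

# ---- full batch forward ----------------------------------------------------

# pairs: data frame with drug_id, protein_id, label for the batch.
# Returns loss node plus diagnostics; `train` toggles dropout.
model_forward <- function(tape, pn, cache, config, pairs, train = TRUE) {
  du <- match(unique(pairs$drug_id), cache$drug_ids)
  pu <- match(unique(pairs$protein_id), cache$prot_ids)
  m <- config$modalities

  zs <- list(drug = list(), target = list())
  if ("structure" %in% m) {
    zs$drug$structure <- forward_drug_structure(tape, pn, cache, du)
    zs$target$structure <- forward_protein_structure(tape, pn, cache, pu)
  }
  if ("sequence" %in% m) {
    zs$drug$sequence <- ad_const(tape, cache$drug_seq[du, , drop = FALSE])
    zs$target$sequence <- ad_const(tape, cache$prot_seq[pu, , drop = FALSE])
  }
  if ("relation" %in% m) {
    zs$drug$relation <- forward_relation(tape, pn$gat_drug, cache$drug_sub,
                                         cache$drug_seq, du)
    zs$target$relation <- forward_relation(tape, pn$gat_prot, cache$prot_sub,
                                           cache$prot_seq, pu)
  }

  proj <- list(drug = list(), target = list())
  for (cls in c("drug", "target")) {
    for (mod in m) {
      proj[[cls]][[mod]] <- ad_project(tape, zs[[cls]][[mod]],
                                       pn$proj[[cls]][[mod]])
    }
  }

  contrast <- NULL
  if (config$use_contrastive && config$lambda > 0 && "sequence" %in% m &&
      length(m) > 1L) {
    terms <- list()
    for (cls in c("drug", "target")) {
      for (mod in setdiff(m, "sequence")) {
        terms[[length(terms) + 1L]] <-
          ad_bidirectional(tape, proj[[cls]]$sequence, proj[[cls]][[mod]],
                           config$tau, config$negative_mode)
      }
    }
    contrast <- terms[[1L]]
    for (i in seq_along(terms)[-1L]) {
      contrast <- ad_add(tape, contrast, terms[[i]])
    }
  }

  soft_weights <- list()
  fused <- list()
  for (cls in c("drug", "target")) {
    Zm <- proj[[cls]][m]
    if (length(Zm) == 1L) {
      fused[[cls]] <- Zm[[1L]]
      soft_weights[[cls]] <- matrix(1, nrow(ad_value(Zm[[1L]])), 1L,
                                    dimnames = list(NULL, m))
    } else if (config$use_soft_attention) {
      sp <- pn$soft[[cls]]
      x <- ad_cbind(tape, Zm)
      h <- ad_linear(tape, x, sp$W1, sp$b1, act = "tanh")
      w <- ad_softmax_rows(tape, ad_linear(tape, h, sp$W2, sp$b2))
      acc <- NULL
      for (i in seq_along(Zm)) {
        term <- ad_rowscale(tape, Zm[[i]], ad_col(tape, w, i))
        acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
      }
      fused[[cls]] <- acc
      soft_weights[[cls]] <- structure(ad_value(w),
                                       dimnames = list(NULL, m))
    } else {
      acc <- Zm[[1L]]
      for (i in seq_along(Zm)[-1L]) acc <- ad_add(tape, acc, Zm[[i]])
      fused[[cls]] <- ad_mulc(tape, acc, 1 / length(Zm))
      soft_weights[[cls]] <- matrix(1 / length(Zm), nrow(ad_value(acc)),
                                    length(Zm), dimnames = list(NULL, m))
    }
  }

  di <- match(pairs$drug_id, cache$drug_ids[du])
  ti <- match(pairs$protein_id, cache$prot_ids[pu])
  zD <- ad_rows(tape, fused$drug, di)
  zT <- ad_rows(tape, fused$target, ti)

  if (config$use_cross_attention) {
    attn <- function(partner, cp) {
      v <- ad_matmul(tape, partner, cp$Wv)       # per-head value projection;
      o <- ad_matmul(tape, v, cp$Wo)             # singleton softmax weight = 1
      ad_linear(tape,
                ad_linear(tape, o, cp$ff_W1, cp$ff_b1, act = "relu"),
                cp$ff_W2, cp$ff_b2)
    }
    zfD <- ad_add(tape, zD, attn(zT, pn$cross$d_to_t))
    zfT <- ad_add(tape, zT, attn(zD, pn$cross$t_to_d))
  } else {
    zfD <- zD
    zfT <- zT
  }

  x <- ad_cbind(tape, list(zfD, zfT))
  h1 <- ad_linear(tape, x, pn$clf$W1, pn$clf$b1, act = "gelu")
  drop_rate <- if (train) pn$clf$dropout else 0
  if (drop_rate > 0) {
    mask1 <- matrix(stats::rbinom(length(ad_value(h1)), 1L, 1 - drop_rate),
                    nrow(ad_value(h1))) / (1 - drop_rate)
    h1 <- ad_mulc(tape, h1, mask1)
  }
  h2 <- ad_linear(tape, h1, pn$clf$W2, pn$clf$b2, act = "gelu")
  if (drop_rate > 0) {
    mask2 <- matrix(stats::rbinom(length(ad_value(h2)), 1L, 1 - drop_rate),
                    nrow(ad_value(h2))) / (1 - drop_rate)
    h2 <- ad_mulc(tape, h2, mask2)
  }
  logit <- ad_linear(tape, h2, pn$clf$W3, pn$clf$b3)

  bce <- ad_bce_logits(tape, logit, pairs$label)
  loss <- if (!is.null(contrast)) {
    ad_add(tape, bce, ad_mulc(tape, contrast, config$lambda))
  } else {
    bce
  }

  list(loss = loss,
       bce = as.numeric(ad_value(bce)),
       contrastive = if (is.null(contrast)) 0 else as.numeric(ad_value(contrast)),
       probs = stats::plogis(as.numeric(ad_value(logit))),
       soft_weights = soft_weights)
}

# Evaluation-mode predictions for arbitrary pairs, in chunks.
predict_pairs <- function(params, cache, config, pairs, chunk = 400L) {
  probs <- numeric(nrow(pairs))
  i <- 1L
  while (i <= nrow(pairs)) {
    j <- min(i + chunk - 1L, nrow(pairs))
    tape <- ad_tape()
    pn <- params_to_nodes(tape, params)
    fw <- model_forward(tape, pn, cache, config,
                        pairs[i:j, , drop = FALSE], train = FALSE)
    probs[i:j] <- fw$probs
    i <- j + 1L
  }
  probs
}

# Wrap every leaf of the nested parameter list in a tape node.
params_to_nodes <- function(tape, params) {
  wrap <- function(x) {
    if (is.list(x)) {
      meta <- c("kernel_sizes", "n_heads", "dropout", "emb_dim", "hidden_dim")
      for (nm in names(x)) {
        if (!nm %in% meta && (is.list(x[[nm]]) || is.numeric(x[[nm]]))) {
          x[[nm]] <- wrap(x[[nm]])
        }
      }
      if (is.null(names(x))) for (i in seq_along(x)) x[[i]] <- wrap(x[[i]])
      x
    } else if (is.numeric(x)) {
      ad_param(tape, x)
    } else {
      x
    }
  }
  wrap(params)
}

# Collect gradients for every parameter node into a flat named list aligned
# with flatten_params(params).
collect_grads <- function(grads, pnodes, prefix = "") {
  out <- list()
  meta <- c("kernel_sizes", "n_heads", "dropout", "emb_dim", "hidden_dim")
  nms <- names(pnodes)
  if (is.null(nms)) nms <- paste0("l", seq_along(pnodes))
  for (i in seq_along(pnodes)) {
    nm <- nms[i]
    if (nm %in% c(meta)) next
    v <- pnodes[[i]]
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (ad_is_node(v)) {
      out[[key]] <- ad_grad(grads, v)
    } else if (is.list(v)) {
      out <- c(out, collect_grads(grads, v, key))
    }
  }
  out
}
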