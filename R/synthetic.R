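# Self-contained synthetic DTI benchmark: molecules, proteins, frozen
# embeddings, a PPI network, and planted interaction labels whose signal is
# distributed across the three modalities in a controlled way.

#' Specification of a synthetic DTI benchmark
#'
#' The defaults define the package's reference study conditions: 60 drugs, 80
#' proteins, ~2000 sampled pairs, logit noise SD 0.5, a 50% positive rate and
#' a (0.3, 0.4, 0.3) structure/sequence/relation signal split.
#'
#' @param n_drugs,n_proteins Entity counts (>= 2).
#' @param n_pairs Number of (drug, protein) pairs sampled from the grid.
#' @param protein_length_range Min/max protein length (residues).
#' @param signal_rank Rank of the bilinear interaction matrix.
#' @param main_effect_frac Fraction of the planted logit variance carried by
#'   entity main effects (drug/protein propensities derived from the same
#'   latents). Real binarized affinity data show strong hub/promiscuity
#'   structure, but main effects are learnable from any modality (they leak
#'   across modalities through correlated observables), which dilutes the
#'   designed separation between single- and tri-modal models; the default
#'   therefore places all planted variance in the interaction term.
#' @param noise_sd SD of the Gaussian noise added to the pair logits.
#' @param positive_rate Target positive-label rate (0, 1).
#' @param modality_signal_split Nonnegative weights over (structure, sequence,
#'   relation) summing to 1; controls how much of the label signal each
#'   modality carries.
#' @param embed_dim Width of the synthetic frozen sequence embeddings.
#' @param top_k Per-node top-k used when sparsifying the relation networks.
#' @param ppi_density Fraction of protein pairs receiving a PPI edge.
#' @param ppi_noise SD of the noise on PPI confidence scores (0-1 scale).
#' @param signal_scale SD to which the planted logits are standardized; the
#'   default 7 makes the labels nearly separable by the true logit, so an
#'   oracle scoring by the planted signal attains a high AUROC ceiling by
#'   construction.
#' @param seed Master seed; all generator substreams derive from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_proteins = 80L, n_pairs = 2000L,
                           protein_length_range = c(64L, 160L),
                           signal_rank = 4L, main_effect_frac = 0,
                           noise_sd = 0.5, positive_rate = 0.5,
                           modality_signal_split = c(structure = 0.3,
                                                     sequence = 0.4,
                                                     relation = 0.3),
                           embed_dim = 64L, top_k = 5L,
                           ppi_density = 0.10, ppi_noise = 0.05,
                           signal_scale = 7, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_proteins >= 2L,
            abs(sum(modality_signal_split) - 1) < 1e-9,
            all(modality_signal_split >= 0),
            noise_sd >= 0, positive_rate > 0, positive_rate < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Seeded sampling helper that never leaks into the caller's RNG stream.
with_seed <- function(seed, expr) {
  rs <- .Random.seed_protect()
  set.seed(seed)
  on.exit(.Random.seed_restore(rs))
  force(expr)
}

smiles_fragments <- function() {
  c("C", "CC", "CCC", "O", "N", "S",
    "C(C)", "C(F)", "C(Cl)", "C(Br)", "C(C)(C)",
    "C(=O)", "C(=O)N", "C(=O)O",
    "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1")
}

#' Generate distinct, chemically valid SMILES strings
#'
#' Molecules are assembled by chaining fragments from a packaged grammar
#' (alkyl chains, rings, common functional groups); every output re-parses
#' through [parse_smiles_to_graph()].
#'
#' @param n Number of molecules.
#' @param seed Integer seed (deterministic output).
#' @return Character vector of `n` distinct SMILES.
#' @export
generate_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  frags <- smiles_fragments()
  out <- character(0)
  with_seed(seed, {
    attempts <- 0L
    max_attempts <- 300L * n
    while (length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("fragment grammar exhausted before reaching n = ", n,
             " distinct molecules (cap ", max_attempts, " attempts)")
      }
      k <- sample(2:6, 1L)
      s <- paste(sample(frags, k, replace = TRUE), collapse = "")
      if (s %in% out) next
      ok <- tryCatch({ parse_smiles_to_graph(s); TRUE },
                     dtifuse_invalid_smiles = function(e) FALSE)
      if (ok) out <- c(out, s)
    }
  })
  out
}

#' Generate protein sequences from latent family profiles
#'
#' Each family has its own position-independent residue-frequency profile;
#' sequences within a family therefore share k-mer statistics and receive
#' higher synthetic-embedding cosine similarity than sequences across
#' families, giving the relational network real structure.
#'
#' @param n Number of sequences.
#' @param length_range Integer min/max sequence length.
#' @param seed Integer seed.
#' @param n_families Number of latent families (default ~ n/20, at least 2).
#' @return Character vector of sequences with a `family` integer attribute.
#' @export
generate_proteins <- function(n, length_range = c(64L, 160L), seed = 1L,
                              n_families = NULL) {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1L] >= 3L, length_range[2L] >= length_range[1L])
  if (is.null(n_families)) n_families <- max(2L, ceiling(n / 20))
  aa <- names(protein_vocab())[1:20]
  with_seed(seed, {
    profiles <- lapply(seq_len(n_families), function(f) {
      w <- stats::rgamma(20L, shape = 0.5)
      w / sum(w)
    })
    family <- sample(rep_len(seq_len(n_families), n))
    seqs <- vapply(seq_len(n), function(i) {
      L <- sample(length_range[1L]:length_range[2L], 1L)
      paste(sample(aa, L, replace = TRUE, prob = profiles[[family[i]]]),
            collapse = "")
    }, "")
    attr(seqs, "family") <- family
    seqs
  })
}

#' Generate a synthetic PPI edge list
#'
#' Edge confidence is the (0-1 scaled) cosine similarity of the protein
#' embeddings plus Gaussian noise; the highest-confidence pairs up to the
#' target density receive edges, with STRING-convention scores in [0, 1000].
#'
#' @param embeddings An [embedding_matrix()] for the proteins.
#' @param density Fraction of all protein pairs that get an edge, in (0, 1].
#' @param noise SD of the confidence noise (on the 0-1 scale).
#' @param seed Integer seed.
#' @return Data frame with columns `a`, `b`, `score`.
#' @export
generate_ppi <- function(embeddings, density = 0.10, noise = 0.05, seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_matrix"),
            density > 0, density <= 1)
  X <- embeddings$vectors
  n <- nrow(X)
  Xn <- X / sqrt(rowSums(X^2))
  S <- Xn %*% t(Xn)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  conf <- (S[idx] + 1) / 2
  with_seed(seed, {
    conf <- conf + stats::rnorm(length(conf), sd = noise)
  })
  m <- max(1L, round(density * nrow(idx)))
  if (m < 1L) stop("density yields zero edges")
  keep <- order(conf, decreasing = TRUE)[seq_len(m)]
  ids <- embeddings$entity_ids
  data.frame(a = ids[idx[keep, 1L]],
             b = ids[idx[keep, 2L]],
             score = round(pmin(pmax(conf[keep], 0), 1) * 1000))
}

#' Plant interaction labels from bilinear entity latents
#'
#' Pair logits combine a rank-r bilinear interaction `u_d' W v_t` with entity
#' main effects (per-drug and per-protein propensities, linear in the same
#' latents), standardized to SD `signal_scale`, plus Gaussian noise. Labels
#' are Bernoulli draws of `sigmoid(logit - b)` where the bias `b` is found by
#' bisection on the realized draws so the empirical positive rate hits the
#' target within 2%; at `noise_sd = 0` labels threshold the logit exactly.
#'
#' @param U,V Numeric latent matrices (drugs x r, proteins x r).
#' @param pairs Two-column integer matrix of (drug index, protein index).
#' @param noise_sd Logit noise SD.
#' @param positive_rate Target positive rate.
#' @param signal_scale SD of the standardized noiseless logits.
#' @param main_effect_frac Fraction of logit variance from entity main
#'   effects (see [synthetic_spec()]).
#' @param seed Integer seed.
#' @return List with `labels` (integer vector), `logit_true` (noiseless
#'   standardized logits, the oracle score), `b`, `W`, `realized_rate`.
#' @export
plant_interactions <- function(U, V, pairs, noise_sd = 0.5,
                               positive_rate = 0.5, signal_scale = 7,
                               main_effect_frac = 0, seed = 1L) {
  U <- as.matrix(U); V <- as.matrix(V)
  r <- ncol(U)
  stopifnot(ncol(V) == r, max(pairs[, 1L]) <= nrow(U),
            max(pairs[, 2L]) <= nrow(V),
            main_effect_frac >= 0, main_effect_frac < 1)
  out <- with_seed(seed, {
    W <- matrix(stats::rnorm(r * r), r, r)
    w_d <- stats::rnorm(r)
    w_t <- stats::rnorm(r)
    Ui <- U[pairs[, 1L], , drop = FALSE]
    Vj <- V[pairs[, 2L], , drop = FALSE]
    std <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-12)
    inter <- std(rowSums((Ui %*% W) * Vj))
    mains <- std(as.numeric(Ui %*% w_d)) + std(as.numeric(Vj %*% w_t))
    raw <- sqrt(1 - main_effect_frac) * inter +
      sqrt(main_effect_frac / 2) * mains
    s <- std(raw) * signal_scale
    eps <- stats::rnorm(length(s), sd = noise_sd)
    u <- stats::runif(length(s))
    list(W = W, s = s, eps = eps, u = u)
  })
  if (noise_sd == 0) {
    # noiseless construction: labels threshold the logit exactly, so the
    # planted signal separates the classes perfectly
    b <- stats::quantile(out$s, 1 - positive_rate, names = FALSE, type = 1L)
    labels <- as.integer(out$s > b)
    realized <- mean(labels)
    if (abs(realized - positive_rate) > 0.02) {
      stop("target positive rate unattainable")
    }
    return(list(labels = labels, logit_true = out$s, b = b, W = out$W,
                realized_rate = realized))
  }
  rate_at <- function(b) mean(out$u < stats::plogis(out$s + out$eps - b))
  lo <- -30; hi <- 30
  if (rate_at(lo) < positive_rate || rate_at(hi) > positive_rate) {
    stop("target positive rate unattainable")
  }
  for (iter in 1:200) {
    b <- (lo + hi) / 2
    if (rate_at(b) >= positive_rate) lo <- b else hi <- b
  }
  b <- lo  # highest b still meeting the rate from above
  realized <- rate_at(b)
  if (abs(realized - positive_rate) > 0.02) {
    stop("bisection could not reach the target positive rate within 2%")
  }
  list(labels = as.integer(out$u < stats::plogis(out$s + out$eps - b)),
       logit_true = out$s, b = b, W = out$W, realized_rate = realized)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(X, 2L, mu), 2L, sdv, "/")
}

# Project a feature block to the latent rank with a seed-fixed Gaussian map,
# then re-standardize, so every modality contributes on a common scale.
latent_from_features <- function(F, rank, seed) {
  F <- standardize_cols(as.matrix(F))
  P <- with_seed(seed, matrix(stats::rnorm(ncol(F) * rank), ncol(F), rank))
  standardize_cols(F %*% P / sqrt(ncol(F)))
}

# Residualize a latent block against previously admitted blocks (plus an
# intercept) so each modality's planted contribution is orthogonal to the
# others across entities - this is what makes single-modality models
# information-limited by construction.
residualize_block <- function(block, against) {
  X <- cbind(1, against)
  resid <- block - X %*% qr.coef(qr(X), block)
  resid[!is.finite(resid)] <- 0
  standardize_cols(resid)
}

# Mix the three modality latent blocks with sequence as the anchor (the
# modality the alignment stage anchors to), orthogonalizing structure and
# relation against it.
mix_modalities <- function(L_struct, L_seq, L_rel, w) {
  L_struct_o <- residualize_block(L_struct, L_seq)
  L_rel_o <- residualize_block(L_rel, cbind(L_seq, L_struct_o))
  sqrt(w[["structure"]]) * L_struct_o +
    sqrt(w[["sequence"]]) * L_seq +
    sqrt(w[["relation"]]) * L_rel_o
}

neighbor_mean_features <- function(network) {
  X <- network$node_features
  out <- X
  e <- network$edges
  for (v in seq_len(nrow(X))) {
    nb <- c(e$j[e$i == v], e$i[e$j == v])
    if (length(nb) > 0L) out[v, ] <- colMeans(X[nb, , drop = FALSE])
  }
  out
}

#' Generate the full synthetic DTI benchmark
#'
#' Produces molecules, proteins, frozen sequence embeddings, sparsified
#' relation networks (drug-drug cosine similarity and a synthetic PPI), and
#' planted labels. Each entity's latent is the stated mixture of its
#' structure-derived features (mean atom features for drugs, residue
#' composition for proteins), its sequence embedding, and its
#' relation-derived features (neighbor-mean embeddings in the sparsified
#' network), weighted by `modality_signal_split` - so single-modality models
#' are information-limited by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_benchmark` with the dataset, entity
#'   tables, embeddings, networks, PPI edges and the ground truth (`$truth`:
#'   planted logits, bias, latents).
#' @export
synthetic_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- as.integer(spec$seed)
  drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
  prot_ids <- sprintf("P%03d", seq_len(spec$n_proteins))

  smiles <- stats::setNames(generate_molecules(spec$n_drugs, seed + 11L),
                            drug_ids)
  seqs <- generate_proteins(spec$n_proteins, spec$protein_length_range,
                            seed + 22L)
  sequences <- stats::setNames(as.character(seqs), prot_ids)

  # splice short motifs into the protein sequences: the structure modality's
  # planted signal is motif presence, the kind of local pattern a multi-scale
  # CNN with global max pooling detects by construction
  aa20 <- names(protein_vocab())[1:20]
  n_motifs <- 16L
  motifs <- with_seed(seed + 88L, vapply(seq_len(n_motifs), function(i) {
    paste(sample(aa20, 5L, replace = TRUE), collapse = "")
  }, ""))
  sequences <- with_seed(seed + 89L, {
    for (i in seq_along(sequences)) {
      s <- sequences[[i]]
      carry <- stats::runif(n_motifs) < 0.5
      for (m in which(carry)) {
        pos <- sample.int(nchar(s) - 4L, 1L)
        substr(s, pos, pos + 4L) <- motifs[m]
      }
      sequences[[i]] <- s
    }
    sequences
  })

  drug_emb <- synthetic_embedding_provider(smiles, spec$embed_dim, seed + 33L)
  prot_emb <- synthetic_embedding_provider(sequences, spec$embed_dim,
                                           seed + 44L)

  drug_net <- topk_sparsify(cosine_similarity_network(drug_emb), spec$top_k)
  ppi_edges <- generate_ppi(prot_emb, spec$ppi_density, spec$ppi_noise,
                            seed + 55L)
  prot_net <- topk_sparsify(ppi_network(ppi_edges, prot_emb), spec$top_k)

  graphs <- lapply(smiles, parse_smiles_to_graph)
  f_struct_d <- t(vapply(graphs, function(g) colMeans(g$atom_features),
                         numeric(ncol(graphs[[1L]]$atom_features))))
  # realized motif presence, computed from the final sequences (splices can
  # overwrite each other, so presence is measured, not assumed)
  f_struct_t <- t(vapply(sequences, function(s) {
    vapply(motifs, function(m) as.numeric(grepl(m, s, fixed = TRUE)), 1)
  }, numeric(n_motifs)))

  f_rel_d <- neighbor_mean_features(drug_net)
  f_rel_t <- neighbor_mean_features(prot_net)

  w <- spec$modality_signal_split
  r <- spec$signal_rank
  U <- mix_modalities(latent_from_features(f_struct_d, r, seed + 101L),
                      latent_from_features(drug_emb$vectors, r, seed + 102L),
                      latent_from_features(f_rel_d, r, seed + 103L), w)
  V <- mix_modalities(latent_from_features(f_struct_t, r, seed + 104L),
                      latent_from_features(prot_emb$vectors, r, seed + 105L),
                      latent_from_features(f_rel_t, r, seed + 106L), w)

  grid_n <- spec$n_drugs * spec$n_proteins
  n_pairs <- min(spec$n_pairs, grid_n)
  pair_lin <- with_seed(seed + 66L, sample.int(grid_n, n_pairs))
  pairs <- cbind(((pair_lin - 1L) %% spec$n_drugs) + 1L,
                 ((pair_lin - 1L) %/% spec$n_drugs) + 1L)

  planted <- plant_interactions(U, V, pairs, spec$noise_sd,
                                spec$positive_rate, spec$signal_scale,
                                spec$main_effect_frac, seed + 77L)

  records <- data.frame(drug_id = drug_ids[pairs[, 1L]],
                        protein_id = prot_ids[pairs[, 2L]],
                        label = planted$labels,
                        stringsAsFactors = FALSE)
  dataset <- interaction_dataset(records, smiles, sequences)

  structure(list(
    dataset = dataset,
    smiles = smiles, sequences = sequences,
    drug_embeddings = drug_emb, protein_embeddings = prot_emb,
    drug_network = drug_net, protein_network = prot_net,
    ppi_edges = ppi_edges,
    truth = list(logit_true = planted$logit_true, b = planted$b,
                 W = planted$W, U = U, V = V,
                 realized_rate = planted$realized_rate,
                 pairs = pairs),
    spec = spec
  ), class = "synthetic_benchmark")
}

#' Write a synthetic benchmark to disk in loader-compatible formats
#'
#' Emits the interaction table (TSV), the PPI edge list (TSV), per-class
#' embedding id/matrix file pairs, and a ground-truth JSON (latents, planted
#' bias) for recovery tests - the same formats the loaders consume.
#'
#' @param benchmark A `synthetic_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- benchmark$dataset$records
  tab <- data.frame(drug_id = rec$drug_id,
                    smiles = unname(benchmark$smiles[rec$drug_id]),
                    protein_id = rec$protein_id,
                    sequence = unname(benchmark$sequences[rec$protein_id]),
                    label = rec$label)
  utils::write.table(tab, file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(benchmark$ppi_edges, file.path(dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  for (cls in c("drug", "protein")) {
    emb <- benchmark[[paste0(cls, "_embeddings")]]
    writeLines(emb$entity_ids, file.path(dir, paste0(cls, "_ids.txt")))
    utils::write.table(emb$vectors, file.path(dir, paste0(cls, "_emb.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(
    list(b = benchmark$truth$b,
         realized_rate = benchmark$truth$realized_rate,
         U = benchmark$truth$U, V = benchmark$truth$V,
         W = benchmark$truth$W,
         pairs = benchmark$truth$pairs,
         logit_true = benchmark$truth$logit_true),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
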