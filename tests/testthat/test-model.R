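# The trainable model: autodiff gradients against finite differences, the
# batched forward against the exported per-entity operations, determinism,
# checkpointing, and ablation switch semantics.

model_fixture <- local({
  cache_obj <- NULL
  function() {
    if (is.null(cache_obj)) {
      bench <- tiny_benchmark()
      cfg <- tiny_config()
      cache <- build_entity_cache(bench$dataset, bench$drug_embeddings,
                                  bench$protein_embeddings, cfg,
                                  bench$ppi_edges)
      params <- dti_params_init(cfg, ncol(cache$drug_seq),
                                ncol(cache$prot_seq))
      cache_obj <<- list(bench = bench, cfg = cfg, cache = cache,
                         params = params,
                         pairs = bench$dataset$records[1:8, ])
    }
    cache_obj
  }
})

forward_loss <- function(fx, flat) {
  p2 <- dtifuse:::unflatten_params(flat, fx$params)
  tape <- dtifuse:::ad_tape()
  pn <- dtifuse:::params_to_nodes(tape, p2)
  fw <- dtifuse:::model_forward(tape, pn, fx$cache, fx$cfg, fx$pairs,
                                train = FALSE)
  as.numeric(dtifuse:::ad_value(fw$loss))
}

test_that("autodiff gradients match finite differences across all components", {
  fx <- model_fixture()
  flat <- dtifuse:::flatten_params(fx$params)
  tape <- dtifuse:::ad_tape()
  pn <- dtifuse:::params_to_nodes(tape, fx$params)
  fw <- dtifuse:::model_forward(tape, pn, fx$cache, fx$cfg, fx$pairs,
                                train = FALSE)
  grads <- dtifuse:::collect_grads(dtifuse:::ad_backward(tape, fw$loss), pn)
  base <- as.numeric(dtifuse:::ad_value(fw$loss))

  set.seed(99)
  keys <- c("gin.l1.eps", "gin.l2.W1", "cnn.emb", "cnn.branches.l3.l2.W",
            "gat_drug.l1.a", "gat_prot.l2.Wl", "proj.drug.sequence.W1",
            "proj.target.relation.B2", "soft.drug.W2", "cross.d_to_t.Wv",
            "cross.t_to_d.ff_W2", "clf.W1", "clf.b3")
  h <- 1e-5
  for (k in keys) {
    i <- sample(length(flat[[k]]), 1L)
    f2 <- flat
    f2[[k]][i] <- f2[[k]][i] + h
    num <- (forward_loss(fx, f2) - base) / h
    expect_equal(grads[[k]][i], num, tolerance = 5e-3,
                 label = paste("grad", k))
  }
  # degenerate softmax: the query projection receives no gradient
  expect_equal(max(abs(grads[["cross.d_to_t.Wq"]])), 0)
})

test_that("the batched forward agrees with the exported per-entity ops", {
  fx <- model_fixture()
  cfg <- fx$cfg
  cache <- fx$cache
  params <- fx$params
  pairs <- fx$pairs
  tape <- dtifuse:::ad_tape()
  pn <- dtifuse:::params_to_nodes(tape, params)
  fw <- dtifuse:::model_forward(tape, pn, cache, cfg, pairs, train = FALSE)

  # reproduce one pair end-to-end with the exported numeric operations
  for (row in c(1L, 5L)) {
    did <- pairs$drug_id[row]
    pid <- pairs$protein_id[row]
    d_i <- match(did, cache$drug_ids)
    p_i <- match(pid, cache$prot_ids)

    g <- cache$graphs[[did]]
    z_struct_d <- encode_drug_structure(g, params$gin)
    z_struct_t <- encode_protein_structure(
      c(cache$tokens[[pid]], integer(8L)), params$cnn)
    z_seq_d <- cache$drug_seq[d_i, ]
    z_seq_t <- cache$prot_seq[p_i, ]
    sub_d <- cache$drug_sub[[d_i]]
    sub_p <- cache$prot_sub[[p_i]]
    # rebuild subgraph objects for the exported encoder
    enc_rel <- function(sub, seqm, gat) {
      H <- seqm[sub$members, , drop = FALSE]
      n <- sub$n
      t1 <- dtifuse:::ad_tape()
      l1 <- dtifuse:::ad_gatv2_layer(t1, dtifuse:::ad_const(t1, H),
                                     sub$src, sub$dst, n, gat[[1L]])
      l2 <- dtifuse:::ad_gatv2_layer(t1, l1, sub$src, sub$dst, n, gat[[2L]])
      colMeans(dtifuse:::ad_value(l2))
    }
    z_rel_d <- enc_rel(sub_d, cache$drug_seq, params$gat_drug)
    z_rel_t <- enc_rel(sub_p, cache$prot_seq, params$gat_prot)

    pj <- function(v, pp) as.numeric(project(matrix(v, 1L), pp))
    zd <- list(structure = pj(z_struct_d, params$proj$drug$structure),
               sequence = pj(z_seq_d, params$proj$drug$sequence),
               relation = pj(z_rel_d, params$proj$drug$relation))
    zt <- list(structure = pj(z_struct_t, params$proj$target$structure),
               sequence = pj(z_seq_t, params$proj$target$sequence),
               relation = pj(z_rel_t, params$proj$target$relation))
    fd <- soft_attention_fuse(zd, params$soft$drug)
    ft <- soft_attention_fuse(zt, params$soft$target)
    fused <- fuse_pair(fd$fused, ft$fused, params$cross)
    want <- classify(fused$z_final_D, fused$z_final_T, params$clf)
    expect_equal(fw$probs[row], want, tolerance = 1e-8)
  }
})

test_that("training is deterministic and aborts cleanly on NaN-free runs", {
  bench <- tiny_benchmark()
  cfg <- tiny_config(seed = 5L)
  split <- random_split(bench$dataset, seed = 5L)
  cache <- build_entity_cache(bench$dataset, bench$drug_embeddings,
                              bench$protein_embeddings, cfg, bench$ppi_edges)
  f1 <- train_dti(bench$dataset, bench$drug_embeddings,
                  bench$protein_embeddings, split, cfg,
                  ppi_edges = bench$ppi_edges, cache = cache)
  f2 <- train_dti(bench$dataset, bench$drug_embeddings,
                  bench$protein_embeddings, split, cfg,
                  ppi_edges = bench$ppi_edges, cache = cache)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$test_metrics, f2$test_metrics)
  expect_all_finite(f1$history$train_loss)
  # epoch-0 equality is implied by identical histories; check epoch 1 loss too
  expect_identical(f1$history$train_loss[1L], f2$history$train_loss[1L])
  # best-model selection: stored val AUROC equals the history maximum
  expect_equal(f1$checkpoint$val_auroc, max(f1$history$val_auroc))
})

test_that("checkpoints round-trip bit-exactly through disk", {
  bench <- tiny_benchmark()
  cfg <- tiny_config(seed = 6L)
  split <- random_split(bench$dataset, seed = 6L)
  cache <- build_entity_cache(bench$dataset, bench$drug_embeddings,
                              bench$protein_embeddings, cfg, bench$ppi_edges)
  fit <- train_dti(bench$dataset, bench$drug_embeddings,
                   bench$protein_embeddings, split, cfg,
                   ppi_edges = bench$ppi_edges, cache = cache)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, tf)
  back <- load_checkpoint(tf)
  expect_identical(back$params, fit$checkpoint$params)

  e1 <- evaluate_dti(fit$checkpoint, bench$dataset, bench$drug_embeddings,
                     bench$protein_embeddings, split, cache = cache)
  e2 <- evaluate_dti(back, bench$dataset, bench$drug_embeddings,
                     bench$protein_embeddings, split, cache = cache)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$metrics, e2$metrics)
  # repeated evaluation (no dropout at eval) is bit-identical
  e3 <- evaluate_dti(back, bench$dataset, bench$drug_embeddings,
                     bench$protein_embeddings, split, cache = cache)
  expect_identical(e2$scores, e3$scores)
})

test_that("ablation switches change exactly what they claim", {
  bench <- tiny_benchmark()
  cfg <- tiny_config(seed = 7L)
  cache <- build_entity_cache(bench$dataset, bench$drug_embeddings,
                              bench$protein_embeddings, cfg, bench$ppi_edges)
  pairs <- bench$dataset$records[1:6, ]

  # single modality: soft-attention weight over that modality is exactly 1
  cfg1 <- cfg; cfg1$modalities <- "sequence"
  p1 <- dti_params_init(cfg1, ncol(cache$drug_seq), ncol(cache$prot_seq))
  t1 <- dtifuse:::ad_tape()
  fw1 <- dtifuse:::model_forward(t1, dtifuse:::params_to_nodes(t1, p1),
                                 cache, cfg1, pairs, train = FALSE)
  expect_true(all(fw1$soft_weights$drug == 1))
  expect_equal(fw1$contrastive, 0)

  # no cross-attention: z_final == z_soft, so removing it must equal a
  # forward whose cross-attention contributes zero
  cfg2 <- cfg; cfg2$use_cross_attention <- FALSE
  p2 <- dti_params_init(cfg, ncol(cache$drug_seq), ncol(cache$prot_seq))
  p2z <- p2
  for (dir in c("d_to_t", "t_to_d")) {
    p2z$cross[[dir]]$Wv[] <- 0
    p2z$cross[[dir]]$ff_W1[] <- 0; p2z$cross[[dir]]$ff_b1[] <- 0
    p2z$cross[[dir]]$ff_W2[] <- 0; p2z$cross[[dir]]$ff_b2[] <- 0
  }
  p2n <- p2; p2n$cross <- NULL
  ta <- dtifuse:::ad_tape()
  fa <- dtifuse:::model_forward(ta, dtifuse:::params_to_nodes(ta, p2z),
                                cache, cfg, pairs, train = FALSE)
  tb <- dtifuse:::ad_tape()
  fb <- dtifuse:::model_forward(tb, dtifuse:::params_to_nodes(tb, p2n),
                                cache, cfg2, pairs, train = FALSE)
  expect_equal(fa$probs, fb$probs, tolerance = 1e-12)

  # disabled soft attention replaces the learned weights with a plain mean
  cfg3 <- cfg; cfg3$use_soft_attention <- FALSE
  p3 <- p2; p3$soft <- NULL
  tc <- dtifuse:::ad_tape()
  fc <- dtifuse:::model_forward(tc, dtifuse:::params_to_nodes(tc, p3),
                                cache, cfg3, pairs, train = FALSE)
  expect_true(all(abs(fc$soft_weights$drug - 1 / 3) < 1e-12))

  # lambda = 0 removes the contrastive term from the total loss
  cfg4 <- cfg; cfg4$lambda <- 0
  td <- dtifuse:::ad_tape()
  fd <- dtifuse:::model_forward(td, dtifuse:::params_to_nodes(td, p2),
                                cache, cfg4, pairs, train = FALSE)
  expect_equal(as.numeric(dtifuse:::ad_value(fd$loss)), fd$bce)
})

test_that("contrastive gradient reaches the projection weights when lambda > 0", {
  fx <- model_fixture()
  cfgL <- fx$cfg; cfgL$lambda <- 0.1
  flat <- dtifuse:::flatten_params(fx$params)
  tape <- dtifuse:::ad_tape()
  pn <- dtifuse:::params_to_nodes(tape, fx$params)
  fw <- dtifuse:::model_forward(tape, pn, fx$cache, cfgL, fx$pairs,
                                train = FALSE)
  grads <- dtifuse:::collect_grads(dtifuse:::ad_backward(tape, fw$loss), pn)
  k <- "proj.drug.structure.W1"
  i <- 3L; h <- 1e-5
  f2 <- flat; f2[[k]][i] <- f2[[k]][i] + h
  p2 <- dtifuse:::unflatten_params(f2, fx$params)
  t2 <- dtifuse:::ad_tape()
  l2 <- dtifuse:::model_forward(t2, dtifuse:::params_to_nodes(t2, p2),
                                fx$cache, cfgL, fx$pairs, train = FALSE)
  num <- (as.numeric(dtifuse:::ad_value(l2$loss)) -
            as.numeric(dtifuse:::ad_value(fw$loss))) / h
  expect_equal(grads[[k]][i], num, tolerance = 5e-3)
  expect_gt(abs(num), 0)
})
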