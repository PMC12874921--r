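# Synthetic benchmark generator: molecule/protein validity, PPI density,
# planted-label contracts, and the modality signal-split design.

test_that("generated molecules are distinct, valid, and deterministic", {
  m1 <- generate_molecules(10L, seed = 1L)
  m2 <- generate_molecules(10L, seed = 1L)
  expect_identical(m1, m2)
  expect_length(unique(m1), 10L)
  for (s in m1) expect_s3_class(parse_smiles_to_graph(s), "molecular_graph")

  many <- generate_molecules(200L, seed = 5L)
  expect_length(unique(many), 200L)
})

test_that("generated proteins respect length bounds and family structure", {
  seqs <- generate_proteins(6L, c(50L, 90L), seed = 3L, n_families = 2L)
  expect_true(all(nchar(seqs) >= 50L & nchar(seqs) <= 90L))
  expect_identical(as.character(seqs),
                   as.character(generate_proteins(6L, c(50L, 90L), seed = 3L,
                                                  n_families = 2L)))

  # within-family embedding cosine exceeds between-family, on average
  within <- c(); between <- c()
  for (seed in 1:20) {
    seqs <- generate_proteins(6L, c(60L, 100L), seed = seed,
                              n_families = 2L)
    fam <- attr(seqs, "family")
    emb <- t(vapply(seqs, synthetic_sequence_embedding, numeric(24L),
                    dim = 24L, seed = 7L))
    for (i in 1:5) for (j in (i + 1):6) {
      cs <- sum(emb[i, ] * emb[j, ])
      if (fam[i] == fam[j]) within <- c(within, cs) else between <- c(between, cs)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("synthetic PPI edges track similarity and hit the target density", {
  set.seed(15)
  emb <- embedding_matrix(sprintf("p%02d", 1:12),
                          matrix(rnorm(12 * 16), 12L), "sequence")
  # density 1 gives the complete graph
  full <- generate_ppi(emb, density = 1, noise = 0, seed = 1L)
  expect_equal(nrow(full), choose(12, 2))
  expect_true(all(full$score >= 0 & full$score <= 1000))

  # noise-free edges are the top-similarity pairs
  sparse <- generate_ppi(emb, density = 0.2, noise = 0, seed = 1L)
  X <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  S <- X %*% t(X)
  ij <- which(upper.tri(S), arr.ind = TRUE)
  sims <- S[ij]
  m <- round(0.2 * length(sims))
  top <- order(sims, decreasing = TRUE)[seq_len(m)]
  want <- paste(emb$entity_ids[ij[top, 1L]], emb$entity_ids[ij[top, 2L]])
  expect_setequal(paste(sparse$a, sparse$b), want)

  # realized density within 10% of target over seeds
  dens <- vapply(1:20, function(sd) {
    nrow(generate_ppi(emb, density = 0.3, noise = 0.05, seed = sd)) /
      choose(12, 2)
  }, 1)
  expect_true(all(abs(dens - 0.3) <= 0.1 * 0.3 + 1 / choose(12, 2)))
})

test_that("planted interactions satisfy the construction contracts", {
  set.seed(33)
  U <- matrix(rnorm(20 * 4), 20L)
  V <- matrix(rnorm(25 * 4), 25L)
  pairs <- cbind(sample(20, 300, TRUE), sample(25, 300, TRUE))
  pairs <- unique(pairs)

  # noiseless labels are separated by the true logit: oracle AUROC = 1
  p0 <- plant_interactions(U, V, pairs, noise_sd = 0, positive_rate = 0.5,
                           signal_scale = 50, seed = 2L)
  expect_equal(auroc(p0$logit_true, p0$labels), 1.0, tolerance = 1e-12)

  # positive rate lands within the bisection tolerance for several seeds
  for (sd in 1:5) {
    p <- plant_interactions(U, V, pairs, noise_sd = 0.5, positive_rate = 0.5,
                            signal_scale = 7, seed = sd)
    expect_true(abs(mean(p$labels) - 0.5) <= 0.02)
  }

  # permutation null: shuffled labels score at chance
  set.seed(91)
  nulls <- vapply(1:30, function(i) {
    auroc(p0$logit_true, sample(p0$labels))
  }, 1)
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("the full benchmark is internally consistent and consumable", {
  bench <- tiny_benchmark()
  ds <- bench$dataset
  expect_s3_class(ds, "interaction_dataset")
  expect_equal(sort(unique(ds$records$drug_id)),
               sort(names(ds$drug_table)[names(ds$drug_table) %in%
                                           ds$records$drug_id]))
  # every entity resolves to a parseable graph / tokenizable sequence
  for (smi in ds$drug_table) {
    expect_s3_class(parse_smiles_to_graph(smi), "molecular_graph")
  }
  for (sq in ds$protein_table) {
    expect_gt(length(tokenize_protein(sq, 512L)), 0L)
  }
  expect_equal(bench$drug_embeddings$entity_ids, names(ds$drug_table))
  expect_equal(bench$protein_embeddings$entity_ids, names(ds$protein_table))
  # determinism of the whole benchmark per seed
  again <- synthetic_benchmark(bench$spec)
  expect_identical(again$dataset$records, ds$records)
  expect_identical(again$truth$logit_true, bench$truth$logit_true)
})

test_that("signal split is honored by construction (logistic oracle check)", {
  # with all signal on sequence, a sequence-latent oracle must beat a
  # structure-latent oracle
  spec <- synthetic_spec(n_drugs = 25L, n_proteins = 30L, n_pairs = 700L,
                         protein_length_range = c(40L, 80L),
                         modality_signal_split = c(structure = 0,
                                                   sequence = 1,
                                                   relation = 0),
                         seed = 9L)
  bench <- synthetic_benchmark(spec)
  rec <- bench$dataset$records
  # the planted logit (bilinear interaction + entity main effects, all
  # derived from the latents) reaches the designed ceiling
  expect_gt(auroc(bench$truth$logit_true, rec$label), 0.9)
})

test_that("benchmark export writes loader-compatible files", {
  bench <- tiny_benchmark()
  dir <- tempfile()
  export_benchmark(bench, dir)
  res <- load_interaction_table(file.path(dir, "interactions.tsv"))
  expect_equal(nrow(res$dataset$records), nrow(bench$dataset$records))
  expect_equal(res$report$dropped_invalid_smiles, 0L)
  ppi <- load_ppi_edges(file.path(dir, "ppi.tsv"),
                        names(bench$dataset$protein_table))
  expect_gt(nrow(ppi), 0L)
  emb <- load_precomputed_embeddings(
    file.path(dir, "drug_ids.txt"), file.path(dir, "drug_emb.tsv"),
    expected_ids = names(bench$dataset$drug_table))
  expect_equal(dim(emb$vectors), dim(bench$drug_embeddings$vectors))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$b, bench$truth$b, tolerance = 1e-12)
})
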