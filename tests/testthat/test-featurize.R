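# Input parsing: SMILES -> molecular graphs, affinity binarization, table and
# PPI loaders, protein tokenization, dataset cache round-trip.

test_that("SMILES parse into molecular graphs with the 79-wide feature layout", {
  cfg <- atom_feature_config()
  expect_equal(cfg$width, 79L)

  methane <- parse_smiles_to_graph("C")
  expect_s3_class(methane, "molecular_graph")
  expect_equal(nrow(methane$atom_features), 1L)
  expect_equal(nrow(methane$bonds), 0L)
  expect_equal(methane$atom_features[1L, 79L], 0)  # not aromatic

  ethane <- parse_smiles_to_graph("CC")
  expect_equal(nrow(ethane$atom_features), 2L)
  expect_equal(unname(ethane$bonds[1L, ]), c(1L, 2L))

  # every atom row is one-hot in each categorical block plus the flag
  blocks <- list(1:45, 46:56, 57:67, 68:78)
  for (b in blocks) {
    expect_true(all(rowSums(ethane$atom_features[, b, drop = FALSE]) == 1))
  }
})

test_that("benzene matches an independent SMILES parser on atom/bond counts", {
  g <- parse_smiles_to_graph("c1ccccc1")
  expect_equal(nrow(g$atom_features), 6L)
  expect_equal(nrow(g$bonds), 6L)
  expect_equal(unname(g$atom_features[, 79L]), rep(1, 6))  # all aromatic

  skip_if_not_installed("ChemmineR")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf("c1ccccc1"))[[1L]]
  expect_equal(nrow(g$atom_features), nrow(ChemmineR::atomblock(sdf)))
  expect_equal(nrow(g$bonds), nrow(ChemmineR::bondblock(sdf)))
})

test_that("graph invariants hold across a set of molecules", {
  for (smi in c("CCO", "c1ccncc1", "CC(=O)Nc1ccccc1", "C1CCCCC1CBr",
                "OC(=O)c1ccccc1O")) {
    g <- parse_smiles_to_graph(smi)
    n <- nrow(g$atom_features)
    expect_gte(n, 1L)
    expect_equal(ncol(g$atom_features), 79L)
    if (nrow(g$bonds) > 0L) {
      expect_true(all(g$bonds <= n))
      expect_true(all(g$bonds[, 1L] != g$bonds[, 2L]))
      expect_false(any(duplicated(paste(g$bonds[, 1L], g$bonds[, 2L]))))
    }
  }
})

test_that("invalid SMILES raise a typed condition carrying the string", {
  err <- tryCatch(parse_smiles_to_graph("C((X"),
                  dtifuse_invalid_smiles = function(e) e)
  expect_s3_class(err, "dtifuse_invalid_smiles")
  expect_equal(err$smiles, "C((X")
  expect_error(parse_smiles_to_graph(""), class = "dtifuse_invalid_smiles")
})

test_that("affinity binarization is a strict threshold at 30", {
  expect_equal(binarize_affinity(29.9), 1L)
  expect_equal(binarize_affinity(30.0), 0L)
  expect_equal(binarize_affinity(0.0), 1L)
  kd <- c(0, 1, 29.999, 30, 30.001, 1e4)
  expect_equal(binarize_affinity(kd), as.integer(kd < 30))
  expect_error(binarize_affinity(-1), "non-negative")
  expect_error(binarize_affinity(NA_real_))
})

test_that("interaction tables load with SMILES filtering and Kd binarization", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tlabel",
               "d1\tCCO\tp1\tACDEF\t1",
               "d2\tnot_a_smiles((\tp1\tACDEF\t0",
               "d3\tc1ccccc1\tp2\tMKLV\t0",
               "d1\tCCO\tp2\tMKLV\t1"), tf)
  res <- load_interaction_table(tf)
  expect_equal(res$report$rows_read, 4L)
  expect_equal(res$report$dropped_invalid_smiles, 1L)
  expect_equal(nrow(res$dataset$records), 3L)
  expect_false("d2" %in% names(res$dataset$drug_table))

  # Kd column route: 10, 30, 100 -> 1, 0, 0
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tkd",
               "d1\tCCO\tp1\tACDEF\t10",
               "d1\tCCO\tp2\tMKLV\t30",
               "d3\tCCN\tp1\tACDEF\t100"), tf2)
  res2 <- load_interaction_table(tf2, schema = list(
    drug_id = "drug_id", smiles = "smiles", protein_id = "protein_id",
    sequence = "sequence", kd = "kd"))
  expect_equal(res2$dataset$records$label, c(1L, 0L, 0L))
})

test_that("duplicate pairs collapse when consistent and error when not", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tlabel",
               "d1\tCCO\tp1\tACDEF\t1",
               "d1\tCCO\tp1\tACDEF\t1"), tf)
  res <- load_interaction_table(tf)
  expect_equal(nrow(res$dataset$records), 1L)
  expect_equal(res$report$duplicates_collapsed, 1L)

  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tlabel",
               "d1\tCCO\tp1\tACDEF\t1",
               "d1\tCCO\tp1\tACDEF\t0"), tf2)
  expect_error(load_interaction_table(tf2), "conflicting labels")
})

test_that("PPI loading subsets to the id universe, symmetrizes and max-dedupes", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("A B 900", "B C 700", "A B 850", "B A 880"), tf)
  e <- load_ppi_edges(tf, id_universe = c("A", "B"))
  expect_equal(nrow(e), 1L)
  expect_equal(e$score, 900)
  expect_equal(c(e$a, e$b), c("A", "B"))

  # brute-force filter oracle on random edges
  set.seed(3)
  ids <- sprintf("n%02d", 1:10)
  a <- sample(ids, 20, replace = TRUE)
  b <- sample(ids, 20, replace = TRUE)
  sc <- sample(100:999, 20)
  keepable <- a != b
  tf2 <- tempfile(fileext = ".txt")
  writeLines(sprintf("%s %s %d", a, b, sc), tf2)
  universe <- ids[1:5]
  got <- load_ppi_edges(tf2, universe)
  want_rows <- which(keepable & a %in% universe & b %in% universe)
  want_keys <- unique(paste(pmin(a, b)[want_rows], pmax(a, b)[want_rows]))
  expect_setequal(paste(got$a, got$b), want_keys)
  for (r in seq_len(nrow(got))) {
    dup <- want_rows[pmin(a, b)[want_rows] == got$a[r] &
                     pmax(a, b)[want_rows] == got$b[r]]
    expect_equal(got$score[r], max(sc[dup]))
  }

  # malformed rows warn but do not abort
  tf3 <- tempfile(fileext = ".txt")
  writeLines(c("A B 900", "garbage-row"), tf3)
  expect_warning(e3 <- load_ppi_edges(tf3, c("A", "B")), "malformed")
  expect_equal(nrow(e3), 1L)
})

test_that("protein tokenization pads, truncates, and maps unknowns to X", {
  v <- protein_vocab()
  expect_equal(tokenize_protein("ACD", 5L),
               c(v[["A"]], v[["C"]], v[["D"]], 0L, 0L))
  expect_equal(length(tokenize_protein("ACDEFG", 3L)), 3L)
  expect_equal(tokenize_protein("ACDEFG", 3L),
               unname(v[c("A", "C", "D")]))
  expect_warning(tk <- tokenize_protein("AZ", 4L), "unknown residues")
  expect_equal(tk[2L], unname(v[["X"]]))
})

test_that("dataset cache round-trips through JSON lines", {
  ds <- toy_dataset()
  tf <- tempfile(fileext = ".jsonl")
  write_dataset_cache(ds, tf)
  back <- read_dataset_cache(tf)
  expect_equal(back$records, ds$records)
  expect_equal(back$drug_table, ds$drug_table)
  expect_equal(back$protein_table, ds$protein_table)
})

test_that("loading the same file twice gives identical datasets", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tlabel",
               "d1\tCCO\tp1\tACDEF\t1",
               "d3\tc1ccccc1\tp2\tMKLV\t0"), tf)
  r1 <- load_interaction_table(tf)
  r2 <- load_interaction_table(tf)
  expect_identical(r1$dataset, r2$dataset)
})
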