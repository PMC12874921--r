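# Shared fixtures: tiny deterministic datasets and parameter sets used across
# the unit tests. Everything is generated in code; nothing is read from disk.

tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_benchmark(synthetic_spec(
        n_drugs = 12L, n_proteins = 15L, n_pairs = 120L,
        protein_length_range = c(40L, 80L), seed = 42L))
    }
    cache
  }
})

tiny_config <- function(seed = 1L, ...) {
  args <- list(gin_dim = 8L, cnn_dim = 8L, gat_dim = 8L, proj_dim = 8L,
               soft_hidden = 8L, cross_heads = 2L, batch_size = 8L,
               max_epochs = 2L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(dti_config, args)
}

# a small random interaction dataset without chemistry (for split tests)
toy_dataset <- function(n_drugs = 8L, n_proteins = 10L, n_pairs = 60L,
                        seed = 7L) {
  set.seed(seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  prots <- sprintf("p%02d", seq_len(n_proteins))
  grid <- expand.grid(drug_id = drugs, protein_id = prots,
                      stringsAsFactors = FALSE)
  rows <- sample(nrow(grid), n_pairs)
  records <- data.frame(drug_id = grid$drug_id[rows],
                        protein_id = grid$protein_id[rows],
                        label = rbinom(n_pairs, 1L, 0.5))
  interaction_dataset(records,
                      stats::setNames(rep("CCO", n_drugs), drugs),
                      stats::setNames(rep("ACDEFGHIK", n_proteins), prots))
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(unlist(x))))
}
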