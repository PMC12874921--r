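# Frozen sequence-embedding providers. The deterministic k-mer provider makes
# the whole pipeline runnable offline; pretrained chemical/protein language
# models are consumed through the adapter as precomputed matrices.

#' Construct an embedding matrix for one entity class
#'
#' @param entity_ids Ordered character vector of entity identifiers.
#' @param vectors Numeric matrix, one row per entity (row order must match
#'   `entity_ids`); no NaN/Inf allowed.
#' @param modality_tag One of `"sequence"`, `"structure"`, `"relation"`.
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(entity_ids, vectors,
                             modality_tag = c("sequence", "structure", "relation")) {
  modality_tag <- match.arg(modality_tag)
  vectors <- as.matrix(vectors)
  stopifnot(length(entity_ids) == nrow(vectors),
            all(is.finite(vectors)))
  rownames(vectors) <- entity_ids
  structure(list(entity_ids = as.character(entity_ids),
                 vectors = vectors,
                 modality_tag = modality_tag,
                 dim = ncol(vectors)),
            class = "embedding_matrix")
}

#' Mean-pool token embeddings into a sequence-level vector
#'
#' Arithmetic mean over unmasked token rows only, the pooling used to turn
#' token-level language-model outputs into per-entity sequence embeddings.
#'
#' @param token_embeddings Numeric matrix (tokens x dim).
#' @param mask Logical vector, `TRUE` for tokens that participate.
#' @return Numeric vector of length `ncol(token_embeddings)`.
#' @export
mean_pool_tokens <- function(token_embeddings,
                             mask = rep(TRUE, nrow(token_embeddings))) {
  token_embeddings <- as.matrix(token_embeddings)
  stopifnot(length(mask) == nrow(token_embeddings), is.logical(mask))
  if (!any(mask)) stop("all token positions are masked")
  colMeans(token_embeddings[mask, , drop = FALSE])
}

# Deterministic 31-bit string hash (polynomial rolling hash).
string_hash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Deterministic synthetic sequence embedding
#'
#' A frozen stand-alone provider: the L1-normalized 3-mer count profile of the
#' sequence is pushed through a seed-fixed random projection (one Gaussian
#' direction per k-mer, derived from a hash of the k-mer and the seed) and
#' L2-normalized. Deterministic in (sequence, dim, seed); sequences sharing
#' most of their k-mers receive high cosine similarity, which gives the
#' relational similarity network meaningful structure.
#'
#' @param sequence Non-empty character string (amino acids or SMILES).
#' @param dim Embedding dimension (>= 2).
#' @param seed Integer seed fixing the random projection.
#' @return Numeric vector of length `dim` with unit L2 norm.
#' @export
synthetic_sequence_embedding <- function(sequence, dim, seed = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (dim < 2L) stop("dim must be >= 2")
  k <- 3L
  s <- sequence
  if (nchar(s) < k) s <- paste(rep(s, k), collapse = "")  # degenerate shorts
  n <- nchar(s)
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  counts <- table(kmers)
  profile <- as.numeric(counts) / sum(counts)
  out <- numeric(dim)
  nm <- names(counts)
  for (i in seq_along(nm)) {
    h <- (string_hash31(nm[i]) + as.integer(seed) %% 100000L * 7919L) %% 2147483647L
    rs <- .Random.seed_protect()
    set.seed(h)
    v <- stats::rnorm(dim)
    .Random.seed_restore(rs)
    out <- out + profile[i] * v
  }
  nrm <- sqrt(sum(out^2))
  if (nrm == 0) stop("degenerate embedding (zero norm)")
  out / nrm
}

# Save/restore the global RNG state so frozen providers never perturb the
# caller's random stream.
.Random.seed_protect <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Synthetic sequence-embedding provider for a set of entities
#'
#' @param sequences Named character vector (names are entity ids).
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return An `embedding_matrix` with `modality_tag = "sequence"`, rows in the
#'   order of `sequences`.
#' @export
synthetic_embedding_provider <- function(sequences, dim = 64L, seed = 1L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  vecs <- t(vapply(sequences, synthetic_sequence_embedding,
                   numeric(dim), dim = dim, seed = seed))
  embedding_matrix(names(sequences), vecs, "sequence")
}

#' Load precomputed sequence embeddings from an ids file and a matrix file
#'
#' The adapter route for pretrained language-model embeddings computed
#' elsewhere: a plain-text ids file (one id per line) paired with a dense
#' whitespace/tab-delimited numeric matrix file with matching row order.
#'
#' @param ids_file Text file of entity ids, one per line.
#' @param matrix_file Delimited numeric matrix, rows aligned with `ids_file`.
#' @param expected_ids Optional character vector; an error listing the missing
#'   ids is raised if any expected id is absent.
#' @return An `embedding_matrix` (rows reordered to `expected_ids` when given).
#' @export
load_precomputed_embeddings <- function(ids_file, matrix_file,
                                        expected_ids = NULL) {
  ids <- readLines(ids_file, warn = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  m <- as.matrix(utils::read.table(matrix_file))
  if (nrow(m) != length(ids)) {
    stop("matrix rows (", nrow(m), ") do not match ids (", length(ids), ")")
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, ids)
    if (length(missing) > 0L) {
      stop("precomputed embeddings missing ids: ",
           paste(missing, collapse = ", "))
    }
    m <- m[match(expected_ids, ids), , drop = FALSE]
    ids <- expected_ids
  }
  embedding_matrix(ids, m, "sequence")
}

#' Pretrained language-model embedding adapter
#'
#' Computes mean-pooled per-entity embeddings with an external pretrained
#' provider (a chemical language model for SMILES, a protein language model
#' for sequences) and caches the matrix on disk keyed by a content hash. The
#' provider executable/runtime is an optional dependency; when it is not
#' available this function stops with instructions to either supply a
#' precomputed matrix ([load_precomputed_embeddings()]) or use the offline
#' synthetic provider ([synthetic_embedding_provider()]).
#'
#' @param sequences Named character vector of sequences.
#' @param provider List with at least `name` (model identifier) and `fn`
#'   (function(sequence) -> token-embedding matrix), or `NULL` when no
#'   provider runtime is installed.
#' @param max_len Length cap; longer sequences are truncated with a warning.
#' @param cache_dir Directory for the on-disk matrix cache.
#' @return An `embedding_matrix`.
#' @export
pretrained_provider <- function(sequences, provider = NULL, max_len = 1024L,
                                cache_dir = tempdir()) {
  if (is.null(provider) || is.null(provider$fn)) {
    stop("no pretrained embedding provider is available in this ",
         "environment; supply a precomputed matrix via ",
         "load_precomputed_embeddings() or use ",
         "synthetic_embedding_provider() instead")
  }
  stopifnot(!is.null(names(sequences)))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- string_hash31(paste(provider$name, max_len,
                             paste(names(sequences), sequences, collapse = ";"),
                             sep = "|"))
  cache_file <- file.path(cache_dir, sprintf("dtifuse_emb_%d.rds", key))
  if (file.exists(cache_file)) {
    return(readRDS(cache_file))
  }
  vecs <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    if (nchar(s) > max_len) {
      warning("sequence '", names(sequences)[i], "' truncated to ", max_len)
      s <- substr(s, 1L, max_len)
    }
    mean_pool_tokens(provider$fn(s))
  })
  out <- embedding_matrix(names(sequences), do.call(rbind, vecs), "sequence")
  saveRDS(out, cache_file)
  out
}
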