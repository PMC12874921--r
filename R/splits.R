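# Evaluation splits: random 7:1:2, repeated-split five-fold protocol, and the
# three cold-start regimes (unseen drug / target / binding).

new_split_assignment <- function(partition, mode, fold_id, seed,
                                 dropped = integer(0)) {
  structure(list(partition = partition, mode = mode, fold_id = fold_id,
                 seed = seed, dropped = dropped),
            class = "split_assignment")
}

#' Random 7:1:2 split of interaction records
#'
#' Shuffles the records with the given seed and assigns
#' `floor(n * ratio)` records to validation and test, the remainder to
#' training. Deterministic per seed.
#'
#' @param dataset An `interaction_dataset`.
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed.
#' @param fold_id Identifier stored with the assignment.
#' @return A `split_assignment`: `partition` is a character vector over record
#'   indices with values in `{"train", "val", "test"}`.
#' @export
random_split <- function(dataset, ratios = c(0.7, 0.1, 0.2), seed = 1L,
                         fold_id = 1L) {
  stopifnot(inherits(dataset, "interaction_dataset"),
            length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9)
  n <- nrow(dataset$records)
  if (n < 3L) stop("dataset too small to split")
  n_val <- floor(n * ratios[2L])
  n_test <- floor(n * ratios[3L])
  n_train <- n - n_val - n_test
  if (n_val < 1L || n_test < 1L || n_train < 1L) {
    stop("a partition would be empty; need more records")
  }
  rs <- .Random.seed_protect()
  set.seed(seed)
  ord <- sample.int(n)
  .Random.seed_restore(rs)
  partition <- character(n)
  partition[ord[seq_len(n_train)]] <- "train"
  partition[ord[n_train + seq_len(n_val)]] <- "val"
  partition[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  new_split_assignment(partition, "random", fold_id, seed)
}

#' Five-fold evaluation protocol
#'
#' Five repeated random 7:1:2 splits with derived seeds (`seed + fold - 1`),
#' matching a mean-and-SD-over-five-folds reporting protocol. A classic
#' disjoint five-fold partition (test folds tile the data; validation carved
#' from the training side) is available with `scheme = "disjoint"`.
#'
#' @param dataset An `interaction_dataset` (at least 10 records).
#' @param seed Base seed.
#' @param scheme `"repeated"` (default) or `"disjoint"`.
#' @return List of five `split_assignment`s.
#' @export
five_fold_cv <- function(dataset, seed = 1L, scheme = c("repeated", "disjoint")) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset$records)
  if (n < 10L) stop("need at least 10 records")
  if (scheme == "repeated") {
    return(lapply(1:5, function(f) {
      random_split(dataset, seed = seed + f - 1L, fold_id = f)
    }))
  }
  rs <- .Random.seed_protect()
  set.seed(seed)
  ord <- sample.int(n)
  .Random.seed_restore(rs)
  fold_of <- rep(1:5, length.out = n)[order(ord)]
  lapply(1:5, function(f) {
    partition <- rep("train", n)
    partition[fold_of == f] <- "test"
    train_idx <- which(fold_of != f)
    rs2 <- .Random.seed_protect()
    set.seed(seed + 100L + f)
    val_idx <- sample(train_idx, max(1L, floor(n * 0.1)))
    .Random.seed_restore(rs2)
    partition[val_idx] <- "val"
    new_split_assignment(partition, "random", f, seed)
  })
}

#' Cold-start splits: unseen drug, unseen target, unseen binding
#'
#' Entities (not pairs) are partitioned 7:1:2 and pairs follow their entity:
#' under `unseen_drug` no test-set drug occurs in training or validation
#' (symmetrically for `unseen_target`). Under `unseen_binding` both entity
#' classes are partitioned and a pair is kept only when its drug and protein
#' fall in the same partition; crossing pairs are dropped and counted.
#'
#' @param dataset An `interaction_dataset`.
#' @param mode One of `"unseen_drug"`, `"unseen_target"`, `"unseen_binding"`.
#' @param ratios Entity-level train/val/test proportions.
#' @param seed Integer seed.
#' @param fold_id Identifier stored with the assignment.
#' @return A `split_assignment`; dropped pair indices (unseen_binding only)
#'   are recorded in `$dropped` and carry partition value `"drop"`.
#' @export
cold_split <- function(dataset,
                       mode = c("unseen_drug", "unseen_target", "unseen_binding"),
                       ratios = c(0.7, 0.1, 0.2), seed = 1L, fold_id = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "interaction_dataset"))
  rec <- dataset$records

  split_entities <- function(ids, seed_offset) {
    ids <- sort(unique(ids))
    m <- length(ids)
    n_val <- floor(m * ratios[2L]); n_test <- floor(m * ratios[3L])
    n_train <- m - n_val - n_test
    if (min(n_train, n_val, n_test) < 1L) {
      stop("not enough distinct entities for a ", mode, " split")
    }
    rs <- .Random.seed_protect()
    set.seed(seed + seed_offset)
    ord <- sample.int(m)
    .Random.seed_restore(rs)
    part <- character(m)
    part[ord[seq_len(n_train)]] <- "train"
    part[ord[n_train + seq_len(n_val)]] <- "val"
    part[ord[n_train + n_val + seq_len(n_test)]] <- "test"
    stats::setNames(part, ids)
  }

  if (mode == "unseen_drug") {
    ep <- split_entities(rec$drug_id, 0L)
    partition <- unname(ep[rec$drug_id])
  } else if (mode == "unseen_target") {
    ep <- split_entities(rec$protein_id, 1L)
    partition <- unname(ep[rec$protein_id])
  } else {
    dp <- split_entities(rec$drug_id, 0L)
    tp <- split_entities(rec$protein_id, 1L)
    pd <- unname(dp[rec$drug_id]); pt <- unname(tp[rec$protein_id])
    partition <- ifelse(pd == pt, pd, "drop")
  }
  dropped <- which(partition == "drop")
  for (p in c("train", "val", "test")) {
    if (!any(partition == p)) {
      stop("cold split produced an empty ", p,
           " partition; try a different seed")
    }
  }
  new_split_assignment(partition, mode, fold_id, seed, dropped)
}

#' Serialize split assignments to JSON lines
#'
#' One JSON object per record (index, partition, fold, mode, seed), making a
#' run's splits exactly reproducible and auditable.
#'
#' @param assignment A `split_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(assignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(assignment$partition)) {
    writeLines(jsonlite::toJSON(list(record = i,
                                     partition = assignment$partition[i],
                                     fold = assignment$fold_id,
                                     mode = assignment$mode,
                                     seed = assignment$seed),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  objs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  partition <- vapply(objs, function(o) o$partition, "")
  new_split_assignment(partition,
                       mode = objs[[1L]]$mode,
                       fold_id = objs[[1L]]$fold,
                       seed = objs[[1L]]$seed,
                       dropped = which(partition == "drop"))
}
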