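# Training orchestration: AdamW optimization of the composite loss,
# per-epoch validation AUROC, best-checkpoint selection, ablation variants,
# and checkpoint round-tripping.

#' Train the tri-modal interaction model
#'
#' Minimizes mean binary cross-entropy plus `lambda` times the cross-modal
#' contrastive loss with AdamW, evaluating validation AUROC after every epoch
#' and returning the parameters that achieved the best validation AUROC
#' (together with test metrics computed under those parameters). Fully
#' deterministic given (config, seed, data).
#'
#' @param dataset An `interaction_dataset`.
#' @param drug_embeddings,protein_embeddings Frozen [embedding_matrix()]s.
#' @param split A `split_assignment` over the dataset's records.
#' @param config A [dti_config()].
#' @param ppi_edges Optional PPI edge list for the protein relation network.
#' @param cache Optional precomputed [build_entity_cache()] (rebuilt when
#'   omitted).
#' @param log_file Optional path; per-epoch JSON lines (losses, validation
#'   AUROC, mean soft-attention weights) are appended when given.
#' @param verbose Print per-epoch progress.
#' @return A list of class `dti_fit`: `checkpoint` (parameters, config,
#'   best validation AUROC and epoch), `history` (per-epoch data frame),
#'   `test_metrics` (from [compute_metrics()] on the test partition) and
#'   `soft_weights` (mean per-modality weights at the last epoch).
#' @export
train_dti <- function(dataset, drug_embeddings, protein_embeddings, split,
                      config = dti_config(), ppi_edges = NULL, cache = NULL,
                      log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "interaction_dataset"),
            inherits(split, "split_assignment"))
  rec <- dataset$records
  stopifnot(length(split$partition) == nrow(rec))
  if (is.null(cache)) {
    cache <- build_entity_cache(dataset, drug_embeddings, protein_embeddings,
                                config, ppi_edges)
  }
  train_idx <- which(split$partition == "train")
  val_idx <- which(split$partition == "val")
  test_idx <- which(split$partition == "test")
  stopifnot(length(train_idx) > 0L, length(val_idx) > 0L)

  params <- dti_params_init(config, ncol(cache$drug_seq), ncol(cache$prot_seq))
  flat <- flatten_params(params)
  opt <- adamw_init(flat)

  best <- list(val_auroc = -Inf, flat = flat, epoch = 0L)
  history <- data.frame()
  rs <- .Random.seed_protect()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(config$seed * 31L + 7L)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0; ep_bce <- 0; ep_con <- 0
    sw_drug <- NULL; sw_target <- NULL; sw_n <- 0L
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * config$batch_size + 1L):
                    min(b * config$batch_size, length(ord))]
      batch <- rec[take, , drop = FALSE]
      tape <- ad_tape()
      pn <- params_to_nodes(tape, unflatten_params(flat, params))
      fw <- model_forward(tape, pn, cache, config, batch, train = TRUE)
      lv <- as.numeric(ad_value(fw$loss))
      if (!is.finite(lv)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " (bce = ", signif(fw$bce, 6),
             ", contrastive = ", signif(fw$contrastive, 6), ")")
      }
      grads <- ad_backward(tape, fw$loss)
      gflat <- collect_grads(grads, pn)
      stepped <- adamw_step(flat, gflat[names(flat)], opt,
                            lr = config$lr,
                            weight_decay = config$weight_decay)
      flat <- stepped$flat
      opt <- stepped$state
      ep_loss <- ep_loss + lv
      ep_bce <- ep_bce + fw$bce
      ep_con <- ep_con + fw$contrastive
      wd <- colMeans(fw$soft_weights$drug)
      wt <- colMeans(fw$soft_weights$target)
      sw_drug <- if (is.null(sw_drug)) wd else sw_drug + wd
      sw_target <- if (is.null(sw_target)) wt else sw_target + wt
      sw_n <- sw_n + 1L
    }
    cur <- unflatten_params(flat, params)
    val_probs <- predict_pairs(cur, cache, config,
                               rec[val_idx, , drop = FALSE])
    val_auroc <- suppressWarnings(auroc(val_probs, rec$label[val_idx]))
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = ep_loss / nb,
      train_bce = ep_bce / nb,
      train_contrastive = ep_con / nb,
      val_auroc = val_auroc
    ))
    if (!is.null(log_file)) {
      line <- jsonlite::toJSON(list(epoch = epoch, train_loss = ep_loss / nb,
                                    train_bce = ep_bce / nb,
                                    train_contrastive = ep_con / nb,
                                    val_auroc = val_auroc,
                                    soft_drug = as.list(sw_drug / sw_n),
                                    soft_target = as.list(sw_target / sw_n)),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = log_file, append = TRUE)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f",
                      epoch, ep_loss / nb, val_auroc))
    }
    if (is.finite(val_auroc) && val_auroc > best$val_auroc) {
      best <- list(val_auroc = val_auroc, flat = flat, epoch = epoch)
    }
  }

  best_params <- unflatten_params(best$flat, params)
  test_metrics <- NULL
  if (length(test_idx) > 0L) {
    probs <- predict_pairs(best_params, cache, config,
                           rec[test_idx, , drop = FALSE])
    test_metrics <- compute_metrics(probs, rec$label[test_idx],
                                    threshold = config$threshold)
  }
  checkpoint <- structure(list(params = best_params, config = config,
                               val_auroc = best$val_auroc,
                               epoch = best$epoch),
                          class = "dti_checkpoint")
  structure(list(checkpoint = checkpoint, history = history,
                 test_metrics = test_metrics,
                 soft_weights = list(drug = sw_drug / sw_n,
                                     target = sw_target / sw_n)),
            class = "dti_fit")
}

#' Evaluate a checkpoint on a split partition
#'
#' Runs the evaluation-mode forward pass (dropout disabled) over the selected
#' partition and computes the metric suite. Repeated evaluation is
#' bit-identical.
#'
#' @param checkpoint A `dti_checkpoint` (from [train_dti()] or
#'   [load_checkpoint()]).
#' @param dataset An `interaction_dataset`.
#' @param drug_embeddings,protein_embeddings Frozen embeddings.
#' @param split A `split_assignment`.
#' @param partition Which partition to score (default `"test"`).
#' @param ppi_edges,cache As in [train_dti()].
#' @return List with `metrics` (from [compute_metrics()]) and `scores`.
#' @export
evaluate_dti <- function(checkpoint, dataset, drug_embeddings,
                         protein_embeddings, split, partition = "test",
                         ppi_edges = NULL, cache = NULL) {
  stopifnot(inherits(checkpoint, "dti_checkpoint"))
  config <- checkpoint$config
  if (is.null(cache)) {
    cache <- build_entity_cache(dataset, drug_embeddings, protein_embeddings,
                                config, ppi_edges)
  }
  idx <- which(split$partition == partition)
  if (length(idx) == 0L) stop("empty partition: ", partition)
  pairs <- dataset$records[idx, , drop = FALSE]
  scores <- predict_pairs(checkpoint$params, cache, config, pairs)
  list(metrics = compute_metrics(scores, pairs$label,
                                 threshold = config$threshold),
       scores = scores, index = idx)
}

#' Train an ablated variant
#'
#' Named variants: `"full"`; `"structure_only"`, `"sequence_only"`,
#' `"relation_only"` (single-modality; soft attention renormalizes to weight 1
#' and the contrastive term vanishes); `"no_contrastive"` (`lambda = 0`);
#' `"no_soft_attention"` (unweighted modality mean); `"no_cross_attention"`
#' (`z_final = z_soft`).
#'
#' @param variant Variant name (see details) or a list overriding
#'   `modalities` / `use_*` switches directly.
#' @inheritParams train_dti
#' @return A `dti_fit` (see [train_dti()]).
#' @export
ablate_dti <- function(dataset, drug_embeddings, protein_embeddings, split,
                       config = dti_config(), variant = "full",
                       ppi_edges = NULL, cache = NULL, verbose = FALSE) {
  cfg <- config
  if (is.character(variant)) {
    variant <- switch(variant,
      full = list(),
      structure_only = list(modalities = "structure"),
      sequence_only = list(modalities = "sequence"),
      relation_only = list(modalities = "relation"),
      no_contrastive = list(use_contrastive = FALSE),
      no_soft_attention = list(use_soft_attention = FALSE),
      no_cross_attention = list(use_cross_attention = FALSE),
      stop("unknown variant: ", variant)
    )
  }
  for (nm in names(variant)) cfg[[nm]] <- variant[[nm]]
  if (length(cfg$modalities) == 0L) stop("empty modality set")
  # a cache built for the full modality set remains valid for subsets
  if (is.null(cache)) {
    cache <- build_entity_cache(dataset, drug_embeddings, protein_embeddings,
                                cfg, ppi_edges)
  }
  train_dti(dataset, drug_embeddings, protein_embeddings, split, cfg,
            ppi_edges = ppi_edges, cache = cache, verbose = verbose)
}

#' Save / load a model checkpoint
#'
#' Round-trips bit-exactly: evaluating a reloaded checkpoint reproduces the
#' original metrics.
#'
#' @param checkpoint A `dti_checkpoint`.
#' @param path File path (RDS).
#' @return `path` invisibly; `load_checkpoint()` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "dti_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "dti_checkpoint"))
  ck
}
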