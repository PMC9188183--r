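# Evaluation protocols: in-dataset evaluation, repeat runs with mean/sd
# aggregation, cross-dataset transfer, parameter sweeps, and checkpoints.

#' Evaluate a fitted model on a split partition
#'
#' @param object a fitted [mffgnn()] model.
#' @param dataset dataset to evaluate on (defaults to the training
#'   dataset).
#' @param splits split bundle (defaults to the model's).
#' @param partition one of `"train"`, `"val"`, `"test"`.
#' @return a `metrics_report` (see [compute_metrics()]).
#' @export
evaluate_model <- function(object, dataset = object$dataset,
                           splits = object$splits, partition = "test") {
  partition <- match.arg(partition, c("train", "val", "test"))
  pos <- splits[[paste0(partition, "_pos")]]
  neg <- splits[[paste0(partition, "_neg")]]
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("empty ", partition, " partition")
  }
  pairs <- rbind(pos, neg)
  labels <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
  inputs <- model_inputs(dataset, object$config, object$vocab)
  scores <- predict_scores(object$params, object$config, inputs,
                           normalize_adjacency(object$A_train), pairs)
  compute_metrics(scores, labels, object$config$f1_threshold,
                  seed = object$config$seed)
}

#' Repeat training over several seeds and aggregate
#'
#' Re-runs fit + test evaluation for each seed and reports per-seed
#' metrics with mean and standard deviation.  `resplit` controls whether
#' each repetition re-randomizes the split as well as the initialization.
#'
#' @param dataset an `interaction_dataset`.
#' @param config an [mffgnn_config()].
#' @param seeds integer vector of seeds.
#' @param resplit if `FALSE`, the split from the first seed is reused.
#' @return data frame with one row per seed plus attribute `summary`
#'   (mean and sd of each metric).
#' @export
run_repeats <- function(dataset, config, seeds = 1:10, resplit = TRUE) {
  base_splits <- if (!resplit) make_splits(dataset, seeds[1L]) else NULL
  rows <- lapply(seeds, function(s) {
    cfg <- validate_config(utils::modifyList(unclass(config),
                                             list(seed = as.integer(s))))
    fit <- mffgnn(dataset, cfg,
                  splits = if (resplit) NULL else base_splits)
    m <- evaluate_model(fit, partition = "test")
    data.frame(seed = s, auroc = m$auroc, auprc = m$auprc, f1 = m$f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("auroc", "auprc", "f1"),
    mean = c(mean(out$auroc), mean(out$auprc), mean(out$f1)),
    sd = c(stats::sd(out$auroc), stats::sd(out$auprc), stats::sd(out$f1)))
  out
}

#' Cross-dataset evaluation
#'
#' Trains on the first dataset with a token vocabulary built from the
#' union of all datasets' corpora, then scores each other dataset's
#' positive pairs plus matched sampled negatives, using that dataset's own
#' adjacency for message passing.  Tokens unseen at training time map to
#' the unknown-token embedding.
#'
#' @param train_dataset the training `interaction_dataset`.
#' @param test_datasets list of `interaction_dataset`s to transfer to.
#' @param config an [mffgnn_config()].
#' @return list with the fitted `model` and `reports`, one
#'   `metrics_report` per test dataset.
#' @export
cross_dataset_eval <- function(train_dataset, test_datasets, config) {
  stopifnot(length(test_datasets) >= 1L)
  corpus <- c(train_dataset$tokens,
              unlist(lapply(test_datasets, `[[`, "tokens"),
                     recursive = FALSE))
  vocab <- fit_vocabulary(train_dataset$tokens)
  shared <- unique(unlist(corpus))
  if (!any(shared %in% names(vocab))) {
    stop("no vocabulary overlap between training and test chemistry")
  }
  fit <- mffgnn(train_dataset, config)
  reports <- lapply(seq_along(test_datasets), function(k) {
    ds <- test_datasets[[k]]
    pos <- ds$positive_pairs
    if (nrow(pos) < 1L) stop("test dataset ", k, " has no positives")
    neg <- with_seed(config$seed + k, {
      ne <- all_nonedges(ds$adjacency)
      ne[sample.int(nrow(ne), min(nrow(pos), nrow(ne))), , drop = FALSE]
    })
    pairs <- rbind(pos, neg)
    labels <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
    inputs <- model_inputs(ds, fit$config, fit$vocab)
    # the external dataset's own (full) adjacency drives message passing
    scores <- predict_scores(fit$params, fit$config, inputs,
                             normalize_adjacency(ds$adjacency), pairs)
    compute_metrics(scores, labels, fit$config$f1_threshold,
                    seed = config$seed)
  })
  list(model = fit, reports = reports)
}

#' Hyperparameter sweep
#'
#' One train + test evaluation per grid point, holding everything not in
#' the grid at the base configuration.
#'
#' @param grid named list of value vectors over any subset of
#'   `alpha, L_s, d_g, lr0, L_gcn, K` (and other config fields).
#' @param dataset an `interaction_dataset`.
#' @param config base configuration.
#' @param out optional CSV path for the tidy results table.
#' @return data frame: one row per grid point with its settings and test
#'   metrics.
#' @export
run_sweep <- function(grid, dataset, config = mffgnn_config(), out = NULL) {
  stopifnot(is.list(grid), length(grid) > 0L, !is.null(names(grid)))
  points <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(points)), function(i) {
    upd <- as.list(points[i, , drop = FALSE])
    cfg <- validate_config(utils::modifyList(unclass(config), upd))
    fit <- mffgnn(dataset, cfg)
    m <- evaluate_model(fit, partition = "test")
    cbind(points[i, , drop = FALSE],
          data.frame(seed = cfg$seed, auroc = m$auroc, auprc = m$auprc,
                     f1 = m$f1))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding parameters,
#' configuration, vocabulary, splits and training history.
#'
#' @param object a fitted [mffgnn()] model.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `mffgnn` object (load).
#' @export
save_mffgnn <- function(object, path) {
  stopifnot(inherits(object, "mffgnn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_mffgnn
#' @export
load_mffgnn <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "mffgnn")) stop("not an mffgnn checkpoint: ", path)
  object
}
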