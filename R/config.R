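# Model configuration and ablation variants.

#' Model configuration
#'
#' Collects every hyperparameter and ablation switch in one validated
#' record.  Defaults follow the reference experimental setup: 256-d atom
#' and drug representations, 2 attention heads, dropout 0.3, initial
#' learning rate 1e-4 with multiplicative decay 0.96 per epoch,
#' contrastive weight 0.9, sequence length 150.
#'
#' @param d_h atom/bond/token embedding width.
#' @param d_g drug representation width.
#' @param K attention heads in the molecular-graph transmitter.
#' @param L_mol molecular-graph encoder layers.
#' @param L_gcn fusion GCN layers over the DDI network.
#' @param L_s fixed token-sequence length (padding/cutting target).
#' @param dropout dropout rate on intermediate layer outputs, in `[0, 1)`.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative learning-rate factor per epoch.
#' @param alpha weight of the contrastive loss in the joint objective.
#' @param use_gwu include the supernode/transmitter/warp-gate/GRU path
#'   (`FALSE` is the "-GWU" ablation: mean-pooled atom states).
#' @param use_gating include the per-layer gate in the fusion GCN.
#' @param use_contrastive include the contrastive term (`FALSE` sets its
#'   weight to zero).
#' @param feature_set non-empty subset of `c("S","M","I")`: SMILES
#'   sequence, molecular graph, and interaction(identity) features fused
#'   into the initial DDI node matrix.
#' @param seed integer seed controlling initialization, splits made by the
#'   fitter, dropout and negative resampling.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation AUROC.
#' @param mlp_hidden hidden width of the two-layer pair scorer
#'   (default `d_g`).
#' @param f1_threshold decision threshold for the F1 metric.
#' @param resample_negatives if `TRUE`, supervised negatives are resampled
#'   each epoch instead of fixed at split time.
#' @param keep_best if `TRUE` (default) return the parameters with the best
#'   validation AUROC; if `FALSE` return the final-epoch parameters.
#' @param eval_every validate every this many epochs.
#' @return an object of class `mffgnn_config` (a validated named list).
#' @export
mffgnn_config <- function(d_h = 256L, d_g = 256L, K = 2L, L_mol = 2L,
                          L_gcn = 3L, L_s = 150L, dropout = 0.3,
                          lr0 = 1e-4, lr_decay = 0.96, alpha = 0.9,
                          use_gwu = TRUE, use_gating = TRUE,
                          use_contrastive = TRUE,
                          feature_set = c("S", "M", "I"), seed = 1L,
                          epochs = 300L, patience = 30L,
                          mlp_hidden = d_g, f1_threshold = 0.5,
                          resample_negatives = FALSE, eval_every = 1L,
                          keep_best = TRUE) {
  cfg <- list(d_h = as.integer(d_h), d_g = as.integer(d_g),
              K = as.integer(K), L_mol = as.integer(L_mol),
              L_gcn = as.integer(L_gcn), L_s = as.integer(L_s),
              dropout = dropout, lr0 = lr0, lr_decay = lr_decay,
              alpha = alpha, use_gwu = isTRUE(use_gwu),
              use_gating = isTRUE(use_gating),
              use_contrastive = isTRUE(use_contrastive),
              feature_set = unique(as.character(feature_set)),
              seed = as.integer(seed), epochs = as.integer(epochs),
              patience = as.integer(patience),
              mlp_hidden = as.integer(mlp_hidden),
              f1_threshold = f1_threshold,
              resample_negatives = isTRUE(resample_negatives),
              eval_every = as.integer(eval_every),
              keep_best = isTRUE(keep_best))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$d_h >= 1L, cfg$d_g >= 1L, cfg$K >= 1L, cfg$L_mol >= 1L,
            cfg$L_gcn >= 1L, cfg$L_s >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$alpha >= 0, cfg$lr0 > 0, cfg$lr_decay > 0,
            cfg$epochs >= 1L, cfg$patience >= 1L, cfg$mlp_hidden >= 1L,
            cfg$f1_threshold > 0, cfg$f1_threshold < 1)
  if (length(cfg$feature_set) == 0L ||
      !all(cfg$feature_set %in% c("S", "M", "I"))) {
    stop("feature_set must be a non-empty subset of S, M, I")
  }
  structure(cfg, class = "mffgnn_config")
}

#' @export
print.mffgnn_config <- function(x, ...) {
  ab <- c(if (!x$use_gwu) "-GWU", if (!x$use_gating) "-Gating",
          if (!x$use_contrastive) "-Contrastive")
  cat(sprintf(
    "mffgnn config: d_h=%d d_g=%d K=%d L_mol=%d L_gcn=%d L_s=%d\n",
    x$d_h, x$d_g, x$K, x$L_mol, x$L_gcn, x$L_s))
  cat(sprintf("  dropout=%.2f lr0=%g decay=%.2f alpha=%.2f seed=%d\n",
              x$dropout, x$lr0, x$lr_decay, x$alpha, x$seed))
  cat(sprintf("  features={%s}%s\n", paste(x$feature_set, collapse = ","),
              if (length(ab)) paste0(" ablations: ", paste(ab, collapse = " "))
              else ""))
  invisible(x)
}

#' Build an ablation variant of a configuration
#'
#' @param config an [mffgnn_config()].
#' @param ablate character vector among `"gwu"`, `"gating"`,
#'   `"contrastive"`; each named component is switched off.
#' @param features optional replacement `feature_set`.
#' @return the modified, re-validated configuration.
#' @export
build_variant <- function(config, ablate = character(0), features = NULL) {
  stopifnot(inherits(config, "mffgnn_config"))
  bad <- setdiff(ablate, c("gwu", "gating", "contrastive"))
  if (length(bad)) stop("unknown ablation: ", paste(bad, collapse = ", "))
  if ("gwu" %in% ablate) config$use_gwu <- FALSE
  if ("gating" %in% ablate) config$use_gating <- FALSE
  if ("contrastive" %in% ablate) config$use_contrastive <- FALSE
  if (!is.null(features)) config$feature_set <- unique(as.character(features))
  validate_config(unclass(config))
}

#' Learning-rate schedule
#'
#' Exponential decay: `lr0 * lr_decay^epoch`.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay per-epoch multiplicative factor.
#' @param epoch number of completed epochs (0 gives `lr0`).
#' @return the learning rate.
#' @export
learning_rate <- function(lr0, lr_decay, epoch) lr0 * lr_decay^epoch
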