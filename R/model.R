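# End-to-end model: intra-drug encoders -> fusion over the DDI network ->
# pair scorer, the joint objective, and the Adam training loop with
# exponential learning-rate decay and early stopping on validation AUROC.

PRED_CLAMP <- 1e-7

# Score a set of drug pairs from the fused node matrix Z.  The pair
# representation is the elementwise product (symmetric by construction);
# the scorer is a two-layer MLP followed by a sigmoid.
score_pairs_node <- function(ctx, Z, pairs) {
  tp <- ctx$tape
  if (any(pairs[, 1L] == pairs[, 2L])) stop("cannot score a self-pair")
  prod <- ad_mul(tp, ad_gather(tp, Z, pairs[, 1L]),
                 ad_gather(tp, Z, pairs[, 2L]))
  hidden <- ad_relu(tp, ad_addbias(tp, ad_mm(tp, prod, pw(ctx, "sc.W1")),
                                   pw(ctx, "sc.b1")))
  logits <- ad_addbias(tp, ad_mm(tp, hidden, pw(ctx, "sc.W2")),
                       pw(ctx, "sc.b2"))
  ad_clamp(tp, ad_sigmoid(tp, logits), PRED_CLAMP, 1 - PRED_CLAMP)
}

# Binary cross-entropy node (summed over the batch's labeled links).
bce_loss_node <- function(ctx, yhat, labels) {
  tp <- ctx$tape
  y <- matrix(labels, ncol = 1L)
  lp <- ad_scale(tp, ad_log(tp, yhat), y)
  ln <- ad_scale(tp, ad_log(tp, ad_one_minus(tp, yhat)), 1 - y)
  ad_scale(tp, ad_sum(tp, ad_add(tp, lp, ln)), -1)
}

#' Binary cross-entropy over labeled links
#'
#' Sum of `-[y log p + (1-y) log(1-p)]` with predictions clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param predictions probabilities in (0,1).
#' @param labels 0/1 labels.
#' @return scalar loss.
#' @export
bce_loss <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  p <- pmin(pmax(predictions, PRED_CLAMP), 1 - PRED_CLAMP)
  -sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Joint training objective
#'
#' @param L_r supervised link loss.
#' @param L_c contrastive loss.
#' @param alpha contrastive weight (`alpha = 0` recovers the supervised
#'   loss alone).
#' @return `L_r + alpha * L_c`.
#' @export
total_loss <- function(L_r, L_c, alpha) {
  stopifnot(alpha >= 0)
  L_r + alpha * L_c
}

# Assemble model inputs that stay fixed across epochs.
model_inputs <- function(dataset, config, vocab) {
  inputs <- list()
  if ("M" %in% config$feature_set) {
    inputs$batch <- mol_batch(dataset$graphs)
  }
  if ("S" %in% config$feature_set) {
    tm <- token_matrix(dataset$tokens, vocab, config$L_s)
    inputs$ids <- tm$ids
    inputs$valid <- tm$valid
  }
  inputs
}

# Full forward pass to the fused node matrix Z (plus H for the
# contrastive term).  `At` is the normalized training adjacency.
model_forward <- function(ctx, inputs, At) {
  tp <- ctx$tape
  cfg <- ctx$config
  parts <- list()
  if ("M" %in% cfg$feature_set) {
    parts$G <- mgfem_forward(ctx, inputs$batch)
  }
  if ("S" %in% cfg$feature_set) {
    parts$S <- ssfem_forward(ctx, inputs$ids, inputs$valid)
  }
  if ("I" %in% cfg$feature_set) {
    parts$I <- pw(ctx, "id.feat")
  }
  H <- parts[[1L]]
  if (length(parts) > 1L) {
    for (k in seq.int(2L, length(parts))) H <- ad_add(tp, H, parts[[k]])
  }
  Z <- mffm_forward(ctx, H, At)
  list(H = H, Z = Z, parts = parts)
}

adjacency_from_pairs <- function(pairs, n) {
  A <- matrix(0, n, n)
  if (nrow(pairs) > 0L) {
    A[pairs] <- 1
    A[pairs[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Fit the multi-type feature-fusion DDI model
#'
#' Trains the full architecture end to end on the training partition of a
#' transductive edge split: molecular-graph encoder (when `"M"` is in the
#' feature set), BiGRU sequence encoder (`"S"`), trainable identity node
#' features (`"I"`), gated GCN fusion over the normalized training
#' adjacency, elementwise-product MLP pair scorer, and the joint objective
#' (binary cross-entropy plus `alpha` times the contrastive alignment
#' loss).  Optimization is Adam with exponential learning-rate decay;
#' the parameters with the best validation AUROC are returned.  Message
#' passing uses training positives only, so held-out edges never leak
#' into the adjacency.
#'
#' @param dataset an `interaction_dataset`.
#' @param config an [mffgnn_config()].
#' @param splits optional `split_bundle`; made with `config$seed` if
#'   missing.
#' @param verbose print per-epoch progress.
#' @return an object of class `mffgnn`: list with `params` (best
#'   parameters), `config`, `vocab`, `splits`, `history` (data frame
#'   `epoch,lr,train_loss,val_auroc`), `best_epoch`, and the training
#'   `dataset`.
#' @examples
#' \donttest{
#' d <- generate_synthetic(12, 2, 0.8, 0.05, seed = 1)
#' cfg <- mffgnn_config(d_h = 8, d_g = 8, L_s = 30, epochs = 3, lr0 = 0.01)
#' fit <- mffgnn(d, cfg)
#' predict(fit)
#' }
#' @export
mffgnn <- function(dataset, config = mffgnn_config(), splits = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(dataset, "interaction_dataset"),
            inherits(config, "mffgnn_config"))
  if (is.null(splits)) splits <- make_splits(dataset, config$seed)
  n <- nrow(dataset$drugs)
  vocab <- fit_vocabulary(dataset$tokens)
  A_train <- adjacency_from_pairs(splits$train_pos, n)
  At <- normalize_adjacency(A_train)

  with_seed(config$seed, {
    params <- init_params(config, atom_dim = 31L, bond_dim = 6L,
                          vocab_size = length(vocab), n_drugs = n)
    inputs <- model_inputs(dataset, config, vocab)
    opt <- adam_state(params)
    alpha_eff <- if (config$use_contrastive) config$alpha else 0

    val_pairs <- rbind(splits$val_pos, splits$val_neg)
    val_labels <- rep(c(1, 0), c(nrow(splits$val_pos), nrow(splits$val_neg)))
    nonedges <- all_nonedges(dataset$adjacency)

    best <- list(auroc = -Inf, params = params, epoch = 0L)
    patience_left <- config$patience
    history <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      lr <- learning_rate(config$lr0, config$lr_decay, epoch - 1L)

      if (config$resample_negatives) {
        idx <- sample.int(nrow(nonedges), nrow(splits$train_pos))
        train_neg <- nonedges[idx, , drop = FALSE]
      } else {
        train_neg <- splits$train_neg
      }
      train_pairs <- rbind(splits$train_pos, train_neg)
      train_labels <- rep(c(1, 0),
                          c(nrow(splits$train_pos), nrow(train_neg)))

      neg_idx <- if (alpha_eff > 0) sample_corruptions(A_train) else NULL

      ctx <- fwd_ctx(params, config, training = TRUE)
      fwd <- model_forward(ctx, inputs, At)
      yhat <- score_pairs_node(ctx, fwd$Z, train_pairs)
      Lr <- bce_loss_node(ctx, yhat, train_labels)
      loss <- Lr
      if (alpha_eff > 0) {
        Lc <- contrastive_loss_node(ctx, fwd$H, fwd$Z, neg_idx)
        loss <- ad_add(ctx$tape, Lr, ad_scale(ctx$tape, Lc, alpha_eff))
      }
      loss_val <- as.numeric(loss$value)
      if (!is.finite(loss_val)) {
        stop("non-finite training loss at epoch ", epoch,
             " (lr=", lr, "); aborting")
      }
      ad_backward(ctx$tape, loss)
      params <- adam_step(params, ctx_grads(ctx), opt, lr)

      val_auroc <- NA_real_
      if (epoch %% config$eval_every == 0L || epoch == config$epochs) {
        val_scores <- predict_scores(params, config, inputs, At, val_pairs)
        val_auroc <- auroc(val_scores, val_labels)
        if (val_auroc > best$auroc) {
          best <- list(auroc = val_auroc, params = params, epoch = epoch)
          patience_left <- config$patience
        } else {
          patience_left <- patience_left - config$eval_every
        }
      }
      history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = loss_val,
                                     val_auroc = val_auroc)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.3g  loss %.4f  val AUROC %s",
                        epoch, lr, loss_val,
                        ifelse(is.na(val_auroc), "-",
                               sprintf("%.4f", val_auroc))))
      }
      if (patience_left <= 0L) break
    }

    if (!config$keep_best) {
      best <- list(auroc = utils::tail(stats::na.omit(
        vapply(history, function(h) h$val_auroc, numeric(1))), 1L),
        params = params, epoch = epoch)
    }

    structure(list(params = best$params, config = config, vocab = vocab,
                   splits = splits, history = do.call(rbind, history),
                   best_epoch = best$epoch, best_val_auroc = best$auroc,
                   dataset = dataset, A_train = A_train),
              class = "mffgnn")
  })
}

# Evaluation-mode scores for arbitrary index pairs.
predict_scores <- function(params, config, inputs, At, pairs) {
  ctx <- fwd_ctx(params, config, training = FALSE)
  fwd <- model_forward(ctx, inputs, At)
  as.vector(score_pairs_node(ctx, fwd$Z, pairs)$value)
}

# Evaluation-mode embeddings of a fitted model.
model_embeddings <- function(object) {
  inputs <- model_inputs(object$dataset, object$config, object$vocab)
  ctx <- fwd_ctx(object$params, object$config, training = FALSE)
  fwd <- model_forward(ctx, inputs, normalize_adjacency(object$A_train))
  list(H = fwd$H$value, Z = fwd$Z$value,
       G = if (!is.null(fwd$parts$G)) fwd$parts$G$value,
       S = if (!is.null(fwd$parts$S)) fwd$parts$S$value)
}

#' Score drug pairs with a fitted model
#'
#' Probability of an interaction for each drug pair, scored symmetrically
#' from the fused network-level representations.
#'
#' @param object a fitted [mffgnn()] model.
#' @param pairs optional pairs to score: a 2-column matrix of drug indices
#'   or a data frame with columns `drug_id_a`, `drug_id_b`.  Defaults to
#'   the test partition (positives then matched negatives).
#' @param ... unused.
#' @return data frame `drug_id_a, drug_id_b, score` (plus `label` when the
#'   default test partition is scored).
#' @export
predict.mffgnn <- function(object, pairs = NULL, ...) {
  labels <- NULL
  if (is.null(pairs)) {
    pairs <- rbind(object$splits$test_pos, object$splits$test_neg)
    labels <- rep(c(1, 0), c(nrow(object$splits$test_pos),
                             nrow(object$splits$test_neg)))
  } else if (is.data.frame(pairs)) {
    ia <- match(as.character(pairs$drug_id_a), object$dataset$drugs$drug_id)
    ib <- match(as.character(pairs$drug_id_b), object$dataset$drugs$drug_id)
    if (anyNA(ia) || anyNA(ib)) stop("pairs reference unknown drug ids")
    pairs <- cbind(ia, ib)
  } else {
    pairs <- as.matrix(pairs)
  }
  inputs <- model_inputs(object$dataset, object$config, object$vocab)
  scores <- predict_scores(object$params, object$config, inputs,
                           normalize_adjacency(object$A_train), pairs)
  out <- data.frame(
    drug_id_a = object$dataset$drugs$drug_id[pairs[, 1L]],
    drug_id_b = object$dataset$drugs$drug_id[pairs[, 2L]],
    score = scores)
  if (!is.null(labels)) out$label <- labels
  out
}
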