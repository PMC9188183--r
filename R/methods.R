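# S3 methods for fitted models.

#' @export
print.mffgnn <- function(x, ...) {
  cat("Multi-type feature-fusion DDI model\n")
  cat(sprintf("  %d drugs, %d training positives; features {%s}\n",
              nrow(x$dataset$drugs), nrow(x$splits$train_pos),
              paste(x$config$feature_set, collapse = ",")))
  cat(sprintf("  trained %d epoch(s); best validation AUROC %.4f at epoch %d\n",
              max(x$history$epoch), x$best_val_auroc, x$best_epoch))
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a fitted [mffgnn()] model.
#' @param ... unused.
#' @return the object, invisibly; prints configuration and validation/test
#'   metrics.
#' @export
summary.mffgnn <- function(object, ...) {
  print(object)
  print(object$config)
  test <- evaluate_model(object, partition = "test")
  cat("Test partition: ")
  print(test)
  invisible(object)
}

#' Extract model parameters
#'
#' @param object a fitted [mffgnn()] model.
#' @param ... unused.
#' @return the named list of parameter matrices.
#' @export
coef.mffgnn <- function(object, ...) object$params

#' Plot the training history
#'
#' Training loss and validation AUROC against epoch.
#'
#' @param x a fitted [mffgnn()] model.
#' @param ... passed to [plot()].
#' @export
plot.mffgnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  ok <- !is.na(h$val_auroc)
  plot(h$epoch[ok], h$val_auroc[ok], type = "l", xlab = "epoch",
       ylab = "validation AUROC", main = "Validation", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Residuals of the fitted pair scores
#'
#' `label - score` on the training pairs.
#'
#' @param object a fitted [mffgnn()] model.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.mffgnn <- function(object, ...) {
  pairs <- rbind(object$splits$train_pos, object$splits$train_neg)
  labels <- rep(c(1, 0), c(nrow(object$splits$train_pos),
                           nrow(object$splits$train_neg)))
  inputs <- model_inputs(object$dataset, object$config, object$vocab)
  scores <- predict_scores(object$params, object$config, inputs,
                           normalize_adjacency(object$A_train), pairs)
  labels - scores
}

#' Simulate interaction indicators from a fitted model
#'
#' Draws Bernoulli interaction indicators from the predicted pair
#' probabilities.
#'
#' @param object a fitted [mffgnn()] model.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param pairs pairs to simulate for (defaults to the test partition, see
#'   [predict.mffgnn()]).
#' @param ... unused.
#' @return data frame of the pairs with `nsim` indicator columns
#'   `sim1, sim2, ...`.
#' @export
simulate.mffgnn <- function(object, nsim = 1, seed = NULL, pairs = NULL,
                            ...) {
  pred <- predict(object, pairs)
  draw <- function() stats::rbinom(nrow(pred), 1L, pred$score)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  sims <- matrix(sims, nrow = nrow(pred))
  colnames(sims) <- paste0("sim", seq_len(nsim))
  cbind(pred[, c("drug_id_a", "drug_id_b", "score")], as.data.frame(sims))
}
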