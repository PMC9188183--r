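# SMILES sequence feature extraction: token embeddings fed through a
# bidirectional GRU; the two directional states are combined per timestep
# by a weighted sum (s_t = W_t s_fwd + V_t s_bwd + b_t), mean-pooled over
# valid positions and passed through a fully connected readout.  Padded
# positions are masked out of both the recurrences and the pooling, so a
# drug's vector is invariant to the padding length.

# ids: n x L_s integer matrix (0 = padding); valid: n-vector of valid
# lengths.  Returns the n x d_g sequence feature node (rows of S).
ssfem_forward <- function(ctx, ids, valid) {
  tp <- ctx$tape
  cfg <- ctx$config
  d <- cfg$d_h
  n <- nrow(ids)
  stopifnot(all(valid >= 1L))
  emb <- pw(ctx, "ss.emb")
  maxlen <- max(valid)

  step <- function(prefix, h, t) {
    x <- ad_gather(tp, emb, ids[, t] + 1L)
    hnew <- gru_cell(ctx, prefix, h, x)
    m <- matrix((t <= valid) * 1, n, d)
    ad_add(tp, ad_scale(tp, hnew, m), ad_scale(tp, h, 1 - m))
  }

  fwd <- vector("list", maxlen)
  h <- ad_const(tp, matrix(0, n, d))
  for (t in seq_len(maxlen)) {
    h <- step("ss.fwd", h, t)
    fwd[[t]] <- h
  }
  bwd <- vector("list", maxlen)
  h <- ad_const(tp, matrix(0, n, d))
  for (t in seq.int(maxlen, 1L)) {
    h <- step("ss.bwd", h, t)
    bwd[[t]] <- h
  }

  Wt <- pw(ctx, "ss.Wt"); Vt <- pw(ctx, "ss.Vt"); bt <- pw(ctx, "ss.bt")
  acc <- NULL
  for (t in seq_len(maxlen)) {
    st <- ad_addbias(tp, ad_add(tp, ad_mm(tp, fwd[[t]], Wt),
                                ad_mm(tp, bwd[[t]], Vt)), bt)
    st <- ad_scale(tp, st, matrix((t <= valid) * 1, n, d))
    acc <- if (is.null(acc)) st else ad_add(tp, acc, st)
  }
  pooled <- ad_scale(tp, acc, matrix(1 / valid, n, d))
  pooled <- ad_dropout(tp, pooled, cfg$dropout, ctx$training)
  ad_addbias(tp, ad_mm(tp, pooled, pw(ctx, "ss.Wro")), pw(ctx, "ss.bro"))
}

# Stack token sequences into the id matrix + valid-length vector.
token_matrix <- function(tokens, vocab, L_s) {
  seqs <- lapply(tokens, function(tk) pad_or_cut(tokens_to_ids(tk, vocab), L_s))
  ids <- do.call(rbind, lapply(seqs, `[[`, "token_ids"))
  valid <- vapply(seqs, `[[`, integer(1L), "valid_length")
  list(ids = ids, valid = valid)
}

#' Embed a token sequence
#'
#' Looks up each token id in the embedding table; padded positions map to
#' the frozen all-zero padding row.
#'
#' @param tokens a `token_sequence` from [pad_or_cut()].
#' @param params parameter list containing the `ss.emb` table.
#' @return a `L_s x d_h` numeric matrix.
#' @export
embed_sequence <- function(tokens, params) {
  emb <- params[["ss.emb"]]
  ids <- tokens$token_ids
  if (any(ids + 1L > nrow(emb))) stop("token id outside the vocabulary")
  emb[ids + 1L, , drop = FALSE]
}

#' Encode one token sequence into its drug feature vector
#'
#' Evaluation-mode BiGRU encoding of a single sequence.
#'
#' @param tokens a `token_sequence`.
#' @param params parameter list from [init_params()].
#' @param config an [mffgnn_config()].
#' @return numeric vector of length `config$d_g`.
#' @export
bigru_encode <- function(tokens, params, config) {
  if (tokens$valid_length < 1L) stop("sequence has no valid tokens")
  ctx <- fwd_ctx(params, config, training = FALSE)
  S <- ssfem_forward(ctx, matrix(tokens$token_ids, 1L),
                     tokens$valid_length)
  as.vector(S$value)
}

#' Load a user-supplied token embedding dictionary
#'
#' Whitespace-separated text, one `token v1 ... v_dh` entry per line.
#' Matching rows of the (trainable) embedding table are replaced; tokens
#' absent from the vocabulary are ignored.
#'
#' @param params parameter list with an `ss.emb` table.
#' @param vocab vocabulary from [fit_vocabulary()].
#' @param path dictionary file path.
#' @return the updated parameter list.
#' @export
load_embedding_dictionary <- function(params, vocab, path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  d <- ncol(params[["ss.emb"]])
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(parts) != d + 1L) {
      stop("embedding dictionary row has ", length(parts) - 1L,
           " values; expected ", d)
    }
    id <- vocab[parts[1L]]
    if (!is.na(id)) {
      params[["ss.emb"]][id + 1L, ] <- as.numeric(parts[-1L])
    }
  }
  params
}
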