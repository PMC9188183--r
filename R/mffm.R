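# Multi-type feature fusion: intra-drug features H = G + S (with ablation
# variants) used as initial node features of a multi-layer GCN over the
# symmetrically normalized DDI adjacency, a per-layer sigmoid gate
# (highway-style) against over-smoothing, and the contrastive alignment
# loss between intra-drug and network-level representations.

#' Fuse intra-drug feature matrices
#'
#' Elementwise sum of the molecular-graph matrix `G` and the sequence
#' matrix `S` (plain numeric version of the fusion used inside the model).
#'
#' @param G,S conforming `n x d_g` matrices.
#' @return their elementwise sum `H`.
#' @export
fuse_intra <- function(G, S) {
  if (!all(dim(G) == dim(S))) stop("G and S must have identical shape")
  G + S
}

#' Symmetrically normalize an adjacency matrix
#'
#' Adds self-loops and normalizes: `D^{-1/2} (A + I) D^{-1/2}` with
#' `D_ii = sum_j (A + I)_ij`.  The result is symmetric with spectral
#' radius at most 1; isolated nodes keep a unit self-loop.
#'
#' @param A symmetric 0/1 matrix with zero diagonal.
#' @return the normalized adjacency.
#' @export
normalize_adjacency <- function(A) {
  stopifnot(isSymmetric(unname(A)), all(diag(A) == 0))
  AI <- unname(A) + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(AI))
  AI * outer(dinv, dinv)
}

# Gated multi-layer GCN; H and At wrap to tape nodes.  Returns the node Z.
mffm_forward <- function(ctx, H, At) {
  tp <- ctx$tape
  cfg <- ctx$config
  Atn <- ad_const(tp, At)
  Z <- H
  for (r in seq_len(cfg$L_gcn)) {
    pre <- sprintf("ff.r%d", r)
    Ztil <- ad_relu(tp, ad_mm(tp, ad_mm(tp, Atn, Z),
                              pw(ctx, paste0(pre, ".Wu"))))
    Ztil <- ad_dropout(tp, Ztil, cfg$dropout, ctx$training)
    if (cfg$use_gating) {
      gate <- ad_sigmoid(tp, ad_addbias(tp,
                ad_mm(tp, Z, pw(ctx, paste0(pre, ".Wg"))),
                pw(ctx, paste0(pre, ".bg"))))
      Z <- ad_add(tp, ad_mul(tp, Ztil, gate),
                  ad_mul(tp, Z, ad_one_minus(tp, gate)))
    } else {
      Z <- Ztil
    }
  }
  Z
}

#' Encode drugs over the DDI network
#'
#' Plain numeric front-end to the gated GCN encoder: initial node features
#' `H` are propagated through `config$L_gcn` layers over the normalized
#' adjacency of `A` (evaluation mode).
#'
#' @param H `n x d_g` matrix of intra-drug features.
#' @param A symmetric 0/1 interaction adjacency (zero diagonal).
#' @param params parameter list from [init_params()].
#' @param config an [mffgnn_config()].
#' @return the `n x d_g` matrix `Z`.
#' @export
encode_ddi <- function(H, A, params, config) {
  ctx <- fwd_ctx(params, config, training = FALSE)
  Z <- mffm_forward(ctx, ad_const(ctx$tape, H), normalize_adjacency(A))
  Z$value
}

# Sample one non-neighbour per drug (NA when the drug is adjacent to all
# others); consumes the RNG stream.
sample_corruptions <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    cand <- which(A[i, ] == 0)
    cand <- cand[cand != i]
    if (length(cand) == 0L) return(NA_integer_)
    cand[sample.int(length(cand), 1L)]
  }, integer(1L))
}

# Contrastive alignment loss node.  Positive term: -log sigma(h_i . z_i);
# negative term: -log sigma(1 - h~_i . z_i) with h~_i the intra-drug
# feature of one sampled non-neighbour.  Mean over drugs; drugs without a
# possible corruption contribute only their positive term.
contrastive_loss_node <- function(ctx, H, Z, neg_idx) {
  tp <- ctx$tape
  n <- nrow(Z$value)
  pos <- ad_rowsums(tp, ad_mul(tp, H, Z))
  lp <- ad_log(tp, ad_clamp(tp, ad_sigmoid(tp, pos), 1e-12, 1))
  total <- ad_scale(tp, ad_sum(tp, lp), -1)
  ok <- which(!is.na(neg_idx))
  if (length(ok) > 0L) {
    Hneg <- ad_gather(tp, H, neg_idx[ok])
    Zok <- ad_gather(tp, Z, ok)
    sneg <- ad_rowsums(tp, ad_mul(tp, Hneg, Zok))
    ln <- ad_log(tp, ad_clamp(tp,
            ad_sigmoid(tp, ad_one_minus(tp, sneg)), 1e-12, 1))
    total <- ad_add(tp, total, ad_scale(tp, ad_sum(tp, ln), -1))
  }
  ad_scale(tp, total, 1 / n)
}

#' Contrastive alignment loss
#'
#' Numeric front-end: scores agreement (dot product) between each drug's
#' intra-drug vector and its network-level vector against one sampled
#' non-neighbour corruption per drug.
#'
#' @param H,Z row-aligned `n x d_g` matrices.
#' @param A symmetric 0/1 adjacency used to define non-neighbours.
#' @param seed integer seed for the corruption sampling.
#' @return scalar loss (non-negative).
#' @export
contrastive_loss <- function(H, Z, A, seed) {
  stopifnot(all(dim(H) == dim(Z)), nrow(A) == nrow(H))
  neg_idx <- with_seed(seed, sample_corruptions(A))
  if (anyNA(neg_idx)) {
    message(sum(is.na(neg_idx)),
            " drug(s) adjacent to all others: negative term skipped")
  }
  ctx <- fwd_ctx(list(), mffgnn_config(), training = FALSE)
  node <- contrastive_loss_node(ctx, ad_const(ctx$tape, H),
                                ad_const(ctx$tape, Z), neg_idx)
  as.numeric(node$value)
}
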