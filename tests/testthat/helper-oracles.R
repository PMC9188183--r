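# Straight-line, loop-based re-implementations of every model equation,
# kept deliberately independent of the package's vectorized/autodiff path.
# Row-vector convention matches the implementation (states are rows).

o_relu <- function(x) pmax(x, 0)
o_sig <- function(x) 1 / (1 + exp(-x))

o_gru <- function(p, prefix, h, x) {
  g <- function(s) p[[paste0(prefix, s)]]
  z <- o_sig(x %*% g(".Wxz") + h %*% g(".Whz") + as.vector(g(".bz")))
  r <- o_sig(x %*% g(".Wxr") + h %*% g(".Whr") + as.vector(g(".br")))
  n <- tanh(x %*% g(".Wxn") + (r * h) %*% g(".Whn") + as.vector(g(".bn")))
  (1 - z) * n + z * h
}

# Full molecular-graph encoder on one molecule, plain loops.
oracle_mgfem <- function(graph, p, cfg) {
  n <- graph$n_atoms
  d <- cfg$d_h
  V <- matrix(0, n, d)
  for (i in seq_len(n)) {
    V[i, ] <- o_relu(graph$atom_features[i, ] %*% p$mg.Wv0)
  }
  m <- nrow(graph$edges)
  E <- matrix(0, m, d)
  for (k in seq_len(m)) {
    E[k, ] <- o_relu(graph$edge_features[k, ] %*% p$mg.We0)
  }
  g <- matrix(colSums(V), 1L)

  for (l in seq_len(cfg$L_mol)) {
    pre <- sprintf("mg.l%d", l)
    Enew <- matrix(0, m, d)
    for (k in seq_len(m)) {
      i <- graph$edges$src[k]; j <- graph$edges$dst[k]
      Enew[k, ] <- o_relu(c(E[k, ], V[i, ], V[j, ]) %*% p[[paste0(pre, ".We")]] +
                            as.vector(p[[paste0(pre, ".be")]]))
    }
    Vtil <- matrix(0, n, d)
    for (i in seq_len(n)) {
      nbr <- numeric(d)
      for (k in seq_len(m)) {
        if (graph$edges$dst[k] == i) nbr <- nbr + Enew[k, ]
      }
      Vtil[i, ] <- o_relu(c(V[i, ], nbr) %*% p[[paste0(pre, ".Wv")]] +
                            as.vector(p[[paste0(pre, ".bv")]]))
    }
    if (cfg$use_gwu) {
      gtil <- tanh(g %*% p[[paste0(pre, ".Wg")]])
      heads <- NULL
      for (k in seq_len(cfg$K)) {
        logits <- numeric(n)
        for (i in seq_len(n)) {
          o <- tanh(V[i, ] %*% p[[sprintf("%s.Wa1.%d", pre, k)]]) *
            tanh(g %*% p[[sprintf("%s.Wa2.%d", pre, k)]])
          logits[i] <- o %*% p[[sprintf("%s.Wa.%d", pre, k)]]
        }
        a <- exp(logits - max(logits)); a <- a / sum(a)
        hk <- numeric(d)
        for (i in seq_len(n)) hk <- hk + a[i] * V[i, ]
        heads <- c(heads, hk)
      }
      vvs <- tanh(matrix(heads, 1L) %*% p[[paste0(pre, ".Wvs")]])
      gsv <- tanh(g %*% p[[paste0(pre, ".Wsv")]])
      vsi <- matrix(0, n, d)
      for (i in seq_len(n)) {
        gate <- o_sig(Vtil[i, ] %*% p[[paste0(pre, ".Wb1")]] +
                        gsv %*% p[[paste0(pre, ".Wb2")]])
        vsi[i, ] <- (1 - gate) * Vtil[i, ] + gate * gsv
      }
      gate_s <- o_sig(gtil %*% p[[paste0(pre, ".Ws1")]] +
                        vvs %*% p[[paste0(pre, ".Ws2")]])
      gis <- (1 - gate_s) * gtil + gate_s * vvs
      Vn <- matrix(0, n, d)
      for (i in seq_len(n)) {
        Vn[i, ] <- o_gru(p, "mg.gruv", matrix(V[i, ], 1L),
                         matrix(vsi[i, ], 1L))
      }
      V <- Vn
      g <- o_gru(p, "mg.grug", g, gis)
    } else {
      V <- Vtil
    }
    E <- Enew
  }
  pooled <- if (cfg$use_gwu) g else matrix(colMeans(V), 1L)
  as.vector(pooled %*% p$mg.Wro + as.vector(p$mg.bro))
}

# Sequence encoder on one id vector, plain loops.
oracle_ssfem <- function(ids, valid, p) {
  d <- ncol(p$ss.emb)
  hf <- matrix(0, 1L, d)
  fwd <- vector("list", valid)
  for (t in seq_len(valid)) {
    x <- matrix(p$ss.emb[ids[t] + 1L, ], 1L)
    hf <- o_gru(p, "ss.fwd", hf, x)
    fwd[[t]] <- hf
  }
  hb <- matrix(0, 1L, d)
  bwd <- vector("list", valid)
  for (t in seq.int(valid, 1L)) {
    x <- matrix(p$ss.emb[ids[t] + 1L, ], 1L)
    hb <- o_gru(p, "ss.bwd", hb, x)
    bwd[[t]] <- hb
  }
  acc <- matrix(0, 1L, d)
  for (t in seq_len(valid)) {
    acc <- acc + fwd[[t]] %*% p$ss.Wt + bwd[[t]] %*% p$ss.Vt +
      as.vector(p$ss.bt)
  }
  pooled <- acc / valid
  as.vector(pooled %*% p$ss.Wro + as.vector(p$ss.bro))
}

# Gated GCN encoder, per-node sums.
oracle_gcn <- function(H, At, p, cfg) {
  n <- nrow(H)
  Z <- H
  for (r in seq_len(cfg$L_gcn)) {
    pre <- sprintf("ff.r%d", r)
    Zt <- matrix(0, n, ncol(H))
    for (i in seq_len(n)) {
      agg <- numeric(ncol(H))
      for (j in seq_len(n)) agg <- agg + At[i, j] * Z[j, ]
      Zt[i, ] <- o_relu(agg %*% p[[paste0(pre, ".Wu")]])
    }
    if (cfg$use_gating) {
      Zn <- matrix(0, n, ncol(H))
      for (i in seq_len(n)) {
        gate <- o_sig(Z[i, ] %*% p[[paste0(pre, ".Wg")]] +
                        as.vector(p[[paste0(pre, ".bg")]]))
        Zn[i, ] <- Zt[i, ] * gate + Z[i, ] * (1 - gate)
      }
      Z <- Zn
    } else {
      Z <- Zt
    }
  }
  Z
}

# Contrastive alignment loss, per-drug loop.
oracle_contrastive <- function(H, Z, neg_idx) {
  n <- nrow(H)
  total <- 0
  for (i in seq_len(n)) {
    total <- total - log(o_sig(sum(H[i, ] * Z[i, ])))
    if (!is.na(neg_idx[i])) {
      total <- total - log(o_sig(1 - sum(H[neg_idx[i], ] * Z[i, ])))
    }
  }
  total / n
}

# Pair scorer + BCE, per-pair loop.
oracle_score <- function(Z, i, j, p) {
  v <- Z[i, ] * Z[j, ]
  h <- o_relu(v %*% p$sc.W1 + as.vector(p$sc.b1))
  as.numeric(o_sig(h %*% p$sc.W2 + as.vector(p$sc.b2)))
}

oracle_bce <- function(yhat, y) {
  -sum(y * log(yhat) + (1 - y) * log(1 - yhat))
}

# AUROC by exhaustive concordant-pair counting.
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
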