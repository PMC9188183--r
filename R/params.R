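# Parameter initialization, the shared GRU cell, and the Adam optimizer.

# Xavier/Glorot uniform initialization.
xavier <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

zeros_row <- function(d) matrix(0, 1L, d)

gru_param_names <- function(prefix) {
  paste0(prefix, ".", c("Wxz", "Whz", "bz", "Wxr", "Whr", "br",
                        "Wxn", "Whn", "bn"))
}

init_gru <- function(prefix, d_in, d_h) {
  p <- list()
  for (gate in c("z", "r", "n")) {
    p[[paste0(prefix, ".Wx", gate)]] <- xavier(d_in, d_h)
    p[[paste0(prefix, ".Wh", gate)]] <- xavier(d_h, d_h)
    p[[paste0(prefix, ".b", gate)]]  <- zeros_row(d_h)
  }
  p
}

#' Initialize all model parameters
#'
#' Builds the full named list of parameter matrices for a model
#' configuration, Xavier-initialized (biases zero, padding embedding row
#' zero and frozen).  Consumes the R RNG stream; callers seed beforehand.
#'
#' @param config a [mffgnn_config()] object.
#' @param atom_dim,bond_dim input featurization widths.
#' @param vocab_size number of real tokens (excluding padding and the
#'   unknown-token slot).
#' @param n_drugs number of drugs; needed for the identity ("I") node
#'   features when `"I"` is in `config$feature_set`.
#' @return named list of numeric matrices.
#' @keywords internal
init_params <- function(config, atom_dim, bond_dim, vocab_size, n_drugs) {
  d <- config$d_h
  dg <- config$d_g
  K <- config$K
  p <- list()

  if ("M" %in% config$feature_set) {
    p[["mg.Wv0"]] <- xavier(atom_dim, d)
    p[["mg.We0"]] <- xavier(bond_dim, d)
    for (l in seq_len(config$L_mol)) {
      pre <- sprintf("mg.l%d", l)
      p[[paste0(pre, ".We")]] <- xavier(3L * d, d)
      p[[paste0(pre, ".be")]] <- zeros_row(d)
      p[[paste0(pre, ".Wv")]] <- xavier(2L * d, d)
      p[[paste0(pre, ".bv")]] <- zeros_row(d)
      if (config$use_gwu) {
        p[[paste0(pre, ".Wg")]] <- xavier(d, d)
        for (k in seq_len(K)) {
          p[[sprintf("%s.Wa1.%d", pre, k)]] <- xavier(d, d)
          p[[sprintf("%s.Wa2.%d", pre, k)]] <- xavier(d, d)
          p[[sprintf("%s.Wa.%d", pre, k)]]  <- xavier(d, 1L)
        }
        p[[paste0(pre, ".Wvs")]] <- xavier(K * d, d)
        p[[paste0(pre, ".Wsv")]] <- xavier(d, d)
        p[[paste0(pre, ".Wb1")]] <- xavier(d, d)
        p[[paste0(pre, ".Wb2")]] <- xavier(d, d)
        p[[paste0(pre, ".Ws1")]] <- xavier(d, d)
        p[[paste0(pre, ".Ws2")]] <- xavier(d, d)
      }
    }
    if (config$use_gwu) {
      p <- c(p, init_gru("mg.gruv", d, d), init_gru("mg.grug", d, d))
    }
    p[["mg.Wro"]] <- xavier(d, dg)
    p[["mg.bro"]] <- zeros_row(dg)
  }

  if ("S" %in% config$feature_set) {
    # rows: 1 = padding (frozen zero), 2..vocab_size+1 = tokens, last = unknown
    emb <- xavier(vocab_size + 2L, d)
    emb[1L, ] <- 0
    p[["ss.emb"]] <- emb
    p <- c(p, init_gru("ss.fwd", d, d), init_gru("ss.bwd", d, d))
    p[["ss.Wt"]] <- xavier(d, d)
    p[["ss.Vt"]] <- xavier(d, d)
    p[["ss.bt"]] <- zeros_row(d)
    p[["ss.Wro"]] <- xavier(d, dg)
    p[["ss.bro"]] <- zeros_row(dg)
  }

  if ("I" %in% config$feature_set) {
    p[["id.feat"]] <- xavier(n_drugs, dg)
  }

  for (r in seq_len(config$L_gcn)) {
    pre <- sprintf("ff.r%d", r)
    p[[paste0(pre, ".Wu")]] <- xavier(dg, dg)
    if (config$use_gating) {
      p[[paste0(pre, ".Wg")]] <- xavier(dg, dg)
      p[[paste0(pre, ".bg")]] <- zeros_row(dg)
    }
  }

  p[["sc.W1"]] <- xavier(dg, config$mlp_hidden)
  p[["sc.b1"]] <- zeros_row(config$mlp_hidden)
  p[["sc.W2"]] <- xavier(config$mlp_hidden, 1L)
  p[["sc.b2"]] <- zeros_row(1L)
  p
}

# A forward context: tape + lazily wrapped parameter leaves, so each
# parameter matrix is a single tape node per forward pass.
fwd_ctx <- function(params, config, training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- ad_tape()
  ctx$params <- params
  ctx$leaves <- new.env(parent = emptyenv())
  ctx$config <- config
  ctx$training <- training
  ctx
}

pw <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    val <- ctx$params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- ad_leaf(ctx$tape, val)
    ctx$leaves[[name]] <- nd
  }
  nd
}

# Collect d loss / d theta for every parameter touched this forward pass.
ctx_grads <- function(ctx) {
  out <- list()
  for (name in ls(ctx$leaves)) {
    g <- ctx$leaves[[name]]$grad
    if (!is.null(g)) out[[name]] <- g
  }
  out
}

# One GRU step for a batch: h, x are n x d nodes.  Shared across atoms /
# timesteps by reusing the same parameter prefix.
gru_cell <- function(ctx, prefix, h, x) {
  tp <- ctx$tape
  z <- ad_sigmoid(tp, ad_addbias(tp, ad_add(tp,
         ad_mm(tp, x, pw(ctx, paste0(prefix, ".Wxz"))),
         ad_mm(tp, h, pw(ctx, paste0(prefix, ".Whz")))),
         pw(ctx, paste0(prefix, ".bz"))))
  r <- ad_sigmoid(tp, ad_addbias(tp, ad_add(tp,
         ad_mm(tp, x, pw(ctx, paste0(prefix, ".Wxr"))),
         ad_mm(tp, h, pw(ctx, paste0(prefix, ".Whr")))),
         pw(ctx, paste0(prefix, ".br"))))
  n <- ad_tanh(tp, ad_addbias(tp, ad_add(tp,
         ad_mm(tp, x, pw(ctx, paste0(prefix, ".Wxn"))),
         ad_mm(tp, ad_mul(tp, r, h), pw(ctx, paste0(prefix, ".Whn")))),
         pw(ctx, paste0(prefix, ".bn"))))
  one_minus_z <- ad_scale(ctx$tape, ad_sub(tp, z, ad_const(tp,
                   matrix(1, nrow(z$value), ncol(z$value)))), -1)
  ad_add(tp, ad_mul(tp, one_minus_z, n), ad_mul(tp, z, h))
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(x) x * 0)
  st$v <- lapply(params, function(x) x * 0)
  st$t <- 0L
  st
}

# In-place-style Adam update; returns the updated parameter list.  The
# padding embedding row stays frozen at zero.
adam_step <- function(params, grads, st, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (name in names(grads)) {
    g <- grads[[name]]
    if (name == "ss.emb") g[1L, ] <- 0
    st$m[[name]] <- beta1 * st$m[[name]] + (1 - beta1) * g
    st$v[[name]] <- beta2 * st$v[[name]] + (1 - beta2) * g * g
    mhat <- st$m[[name]] / bc1
    vhat <- st$v[[name]] / bc2
    params[[name]] <- params[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
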