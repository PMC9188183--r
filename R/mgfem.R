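# Molecular-graph feature extraction: a graph interaction network
# (edge-then-node updates) interleaved with the graph warp unit -- a
# supernode connected to every atom, a K-head attention transmitter
# shuttling information between atoms and supernode, sigmoid warp gates,
# and shared GRU state updates.  All molecules in a dataset are encoded in
# one batched forward pass; per-molecule membership is carried by index
# vectors.

# Concatenate a list of molecular graphs into one batch.
mol_batch <- function(graphs) {
  n_atoms <- vapply(graphs, `[[`, integer(1L), "n_atoms")
  offs <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  atom_features <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  mol <- rep(seq_along(graphs), n_atoms)
  src <- integer(0); dst <- integer(0)
  edge_features <- matrix(0, 0L, ncol(graphs[[1L]]$edge_features))
  efs <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (nrow(g$edges) == 0L) return(NULL)
    list(src = g$edges$src + offs[i], dst = g$edges$dst + offs[i],
         ef = g$edge_features)
  })
  efs <- Filter(Negate(is.null), efs)
  if (length(efs) > 0L) {
    src <- unlist(lapply(efs, `[[`, "src"))
    dst <- unlist(lapply(efs, `[[`, "dst"))
    edge_features <- do.call(rbind, lapply(efs, `[[`, "ef"))
  }
  list(atom_features = atom_features, edge_features = edge_features,
       src = src, dst = dst, mol = mol, n_mol = length(graphs),
       n_atoms = sum(n_atoms))
}

# Gated convex interpolation: (1 - gate) * a + gate * b.
ad_warp <- function(tape, a, b, gate) {
  ad_add(tape,
         ad_mul(tape, ad_one_minus(tape, gate), a),
         ad_mul(tape, gate, b))
}

# Batched forward pass; returns the n_mol x d_g drug feature node (rows of
# the matrix G).  Extras (per-layer states) are attached for inspection
# when `trace = TRUE`.
mgfem_forward <- function(ctx, batch, trace = FALSE) {
  tp <- ctx$tape
  cfg <- ctx$config
  d <- cfg$d_h
  N <- batch$n_atoms
  has_edges <- length(batch$src) > 0L

  V <- ad_relu(tp, ad_mm(tp, ad_const(tp, batch$atom_features),
                         pw(ctx, "mg.Wv0")))
  E <- if (has_edges) {
    ad_relu(tp, ad_mm(tp, ad_const(tp, batch$edge_features),
                      pw(ctx, "mg.We0")))
  } else NULL
  g <- if (cfg$use_gwu) ad_segsum(tp, V, batch$mol, batch$n_mol) else NULL
  states <- if (trace) list() else NULL

  for (l in seq_len(cfg$L_mol)) {
    pre <- sprintf("mg.l%d", l)
    if (has_edges) {
      Ecat <- ad_cbind(tp, E, ad_gather(tp, V, batch$src),
                       ad_gather(tp, V, batch$dst))
      E <- ad_relu(tp, ad_addbias(tp,
             ad_mm(tp, Ecat, pw(ctx, paste0(pre, ".We"))),
             pw(ctx, paste0(pre, ".be"))))
      # N(i): sum of incoming directed edges (dst == i); every bond is
      # present in both directions so this is undirected aggregation
      nbr <- ad_segsum(tp, E, batch$dst, N)
    } else {
      nbr <- ad_const(tp, matrix(0, N, d))
    }
    Vtil <- ad_relu(tp, ad_addbias(tp,
              ad_mm(tp, ad_cbind(tp, V, nbr), pw(ctx, paste0(pre, ".Wv"))),
              pw(ctx, paste0(pre, ".bv"))))

    if (cfg$use_gwu) {
      gtil <- ad_tanh(tp, ad_mm(tp, g, pw(ctx, paste0(pre, ".Wg"))))
      gm <- ad_gather(tp, g, batch$mol)
      heads <- vector("list", cfg$K)
      alphas <- vector("list", cfg$K)
      for (k in seq_len(cfg$K)) {
        o <- ad_mul(tp,
               ad_tanh(tp, ad_mm(tp, V, pw(ctx, sprintf("%s.Wa1.%d", pre, k)))),
               ad_tanh(tp, ad_mm(tp, gm, pw(ctx, sprintf("%s.Wa2.%d", pre, k)))))
        logits <- ad_mm(tp, o, pw(ctx, sprintf("%s.Wa.%d", pre, k)))
        alpha <- ad_segsoftmax(tp, logits, batch$mol)
        alphas[[k]] <- alpha
        heads[[k]] <- ad_segsum(tp, ad_rowscale(tp, V, alpha),
                                batch$mol, batch$n_mol)
      }
      vvs <- ad_tanh(tp, ad_mm(tp, do.call(ad_cbind, c(list(tp), heads)),
                               pw(ctx, paste0(pre, ".Wvs"))))
      gsv <- ad_tanh(tp, ad_mm(tp, g, pw(ctx, paste0(pre, ".Wsv"))))
      gsv_atoms <- ad_gather(tp, gsv, batch$mol)
      gate_v <- ad_sigmoid(tp, ad_add(tp,
                  ad_mm(tp, Vtil, pw(ctx, paste0(pre, ".Wb1"))),
                  ad_mm(tp, gsv_atoms, pw(ctx, paste0(pre, ".Wb2")))))
      vsi <- ad_warp(tp, Vtil, gsv_atoms, gate_v)
      gate_s <- ad_sigmoid(tp, ad_add(tp,
                  ad_mm(tp, gtil, pw(ctx, paste0(pre, ".Ws1"))),
                  ad_mm(tp, vvs, pw(ctx, paste0(pre, ".Ws2")))))
      gis <- ad_warp(tp, gtil, vvs, gate_s)
      V <- ad_dropout(tp, gru_cell(ctx, "mg.gruv", V, vsi),
                      cfg$dropout, ctx$training)
      g <- ad_dropout(tp, gru_cell(ctx, "mg.grug", g, gis),
                      cfg$dropout, ctx$training)
      if (trace) {
        states[[l]] <- list(V = V, E = E, g = g, alphas = alphas,
                            Vtil = Vtil, gtil = gtil, vvs = vvs, gsv = gsv,
                            gate_v = gate_v, gate_s = gate_s,
                            vsi = vsi, gis = gis)
      }
    } else {
      V <- ad_dropout(tp, Vtil, cfg$dropout, ctx$training)
      if (trace) states[[l]] <- list(V = V, E = E)
    }
  }

  pooled <- if (cfg$use_gwu) {
    g
  } else {
    counts <- tabulate(batch$mol, nbins = batch$n_mol)
    ad_scale(tp, ad_segsum(tp, V, batch$mol, batch$n_mol),
             matrix(1 / counts, batch$n_mol, d))
  }
  G <- ad_addbias(tp, ad_mm(tp, pooled, pw(ctx, "mg.Wro")),
                  pw(ctx, "mg.bro"))
  if (trace) attr(G, "states") <- states
  G
}

#' Encode one molecule into its drug feature vector
#'
#' Runs the molecular-graph encoder (graph interaction network plus graph
#' warp unit) on a single molecule in evaluation mode (no dropout).
#'
#' @param graph a `molecular_graph` from [parse_smiles()].
#' @param params parameter list from [init_params()] (or a fitted model's
#'   `$params`).
#' @param config an [mffgnn_config()].
#' @return numeric vector of length `config$d_g`.
#' @export
encode_molecule <- function(graph, params, config) {
  ctx <- fwd_ctx(params, config, training = FALSE)
  G <- mgfem_forward(ctx, mol_batch(list(graph)))
  as.vector(G$value)
}
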