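# Molecular-graph encoder: straight-line oracle equivalence, closed-form
# unit identities, structural invariances, and gradient reach.

test_that("input projection, supernode init and GRU obey closed forms", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  d <- cfg$d_h

  # ReLU clips negatives through an identity projection
  tp <- mffgnn:::ad_tape()
  x <- mffgnn:::ad_leaf(tp, matrix(c(-1, 2), 1L))
  out <- mffgnn:::ad_relu(tp, mffgnn:::ad_mm(tp, x, mffgnn:::ad_const(tp, diag(2))))
  expect_equal(as.vector(out$value), c(0, 2))

  # supernode init is the atom-state sum, hence permutation-invariant
  g <- parse_smiles("CCO")
  ctx <- mffgnn:::fwd_ctx(p, cfg, training = FALSE)
  batch <- mffgnn:::mol_batch(list(g))
  V0 <- (mffgnn:::ad_relu(ctx$tape, mffgnn:::ad_mm(ctx$tape,
          mffgnn:::ad_const(ctx$tape, batch$atom_features),
          mffgnn:::pw(ctx, "mg.Wv0"))))$value
  tp2 <- mffgnn:::ad_tape()
  gsum <- mffgnn:::ad_segsum(tp2, mffgnn:::ad_leaf(tp2, V0), batch$mol, 1L)
  expect_equal(as.vector(gsum$value), colSums(V0))

  # all-zero GRU parameters with zero state and input give zero output
  pz <- lapply(mffgnn:::init_gru("z", d, d), function(m) m * 0)
  ctxz <- mffgnn:::fwd_ctx(pz, cfg, training = FALSE)
  h <- mffgnn:::gru_cell(ctxz, "z", mffgnn:::ad_const(ctxz$tape, matrix(0, 2L, d)),
                         mffgnn:::ad_const(ctxz$tape, matrix(0, 2L, d)))
  expect_equal(h$value, matrix(0, 2L, d))
})

test_that("vectorized encoder matches the straight-line oracle", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  for (smi in c("CCO", "C", "c1ccc[nH]1", "C(=O)O")) {
    g <- parse_smiles(smi)
    expect_equal(encode_molecule(g, p, cfg), oracle_mgfem(g, p, cfg),
                 tolerance = 1e-6, label = smi)
  }
  # ablated (-GWU) path equals mean-pooled oracle
  cfg2 <- small_config(use_gwu = FALSE)
  p2 <- seeded_params(cfg2)
  g <- parse_smiles("CC(=O)O")
  expect_equal(encode_molecule(g, p2, cfg2), oracle_mgfem(g, p2, cfg2),
               tolerance = 1e-6)
})

test_that("attention weights normalize and gate endpoints interpolate", {
  # softmax of equal logits is uniform; segment softmax sums to 1 per group
  tp <- mffgnn:::ad_tape()
  lg <- mffgnn:::ad_leaf(tp, matrix(c(0.5, 0.5, 0.5, 2, -1), 5L, 1L))
  grp <- c(1L, 1L, 1L, 2L, 2L)
  a <- mffgnn:::ad_segsoftmax(tp, lg, grp)$value
  expect_equal(a[1:3], rep(1 / 3, 3))
  expect_equal(sum(a[4:5]), 1)

  # warp gate at its endpoints returns each fused input exactly
  tp <- mffgnn:::ad_tape()
  A <- matrix(rnorm(6), 2L, 3L); B <- matrix(rnorm(6), 2L, 3L)
  an <- mffgnn:::ad_const(tp, A); bn <- mffgnn:::ad_const(tp, B)
  g0 <- mffgnn:::ad_const(tp, matrix(0, 2L, 3L))
  g1 <- mffgnn:::ad_const(tp, matrix(1, 2L, 3L))
  expect_equal(mffgnn:::ad_warp(tp, an, bn, g0)$value, A)
  expect_equal(mffgnn:::ad_warp(tp, an, bn, g1)$value, B)
  gh <- mffgnn:::ad_const(tp, matrix(0.5, 2L, 3L))
  expect_equal(mffgnn:::ad_warp(tp, an, bn, gh)$value, (A + B) / 2)
  # boundedness: each output coordinate lies between the fused inputs
  gr <- mffgnn:::ad_const(tp, matrix(runif(6), 2L, 3L))
  W <- mffgnn:::ad_warp(tp, an, bn, gr)$value
  expect_true(all(W >= pmin(A, B) - 1e-12 & W <= pmax(A, B) + 1e-12))
})

test_that("attention normalizes per head and layer on real molecules", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  graphs <- lapply(c("CCO", "c1ccccc1", "CC(N)C(=O)O"), parse_smiles)
  ctx <- mffgnn:::fwd_ctx(p, cfg, training = FALSE)
  batch <- mffgnn:::mol_batch(graphs)
  G <- mffgnn:::mgfem_forward(ctx, batch, trace = TRUE)
  for (l in seq_len(cfg$L_mol)) {
    for (k in seq_len(cfg$K)) {
      a <- attr(G, "states")[[l]]$alphas[[k]]$value
      sums <- as.vector(tapply(as.vector(a), batch$mol, sum))
      expect_equal(sums, rep(1, batch$n_mol), tolerance = 1e-6)
    }
  }
  expect_true(all(is.finite(G$value)))
})

test_that("the encoder is invariant to atom relabeling", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  mols <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "CN1CCCC1c1cccnc1",
            "NS(=O)(=O)c1ccccc1", "C1CCNCC1")
  set.seed(99)
  for (smi in mols) {
    g <- parse_smiles(smi)
    ref <- encode_molecule(g, p, cfg)
    for (rep in 1:4) {
      perm <- sample(g$n_atoms)
      gp <- g
      gp$edges <- data.frame(src = perm[g$edges$src], dst = perm[g$edges$dst])
      gp$atom_features <- g$atom_features[order(perm), , drop = FALSE]
      expect_equal(encode_molecule(gp, p, cfg), ref, tolerance = 1e-5,
                   label = paste(smi, "perm", rep))
    }
  }
})

test_that("single atoms encode to finite vectors", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  v <- encode_molecule(parse_smiles("C"), p, cfg)
  expect_length(v, cfg$d_g)
  expect_true(all(is.finite(v)))
})

test_that("gradients reach every on-path parameter of the encoder", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  graphs <- lapply(c("CCO", "c1ccccc1"), parse_smiles)
  ctx <- mffgnn:::fwd_ctx(p, cfg, training = FALSE)
  G <- mffgnn:::mgfem_forward(ctx, mffgnn:::mol_batch(graphs))
  root <- mffgnn:::ad_sum(ctx$tape, mffgnn:::ad_mul(ctx$tape, G, G))
  mffgnn:::ad_backward(ctx$tape, root)
  grads <- mffgnn:::ctx_grads(ctx)
  # with the supernode readout, the last layer's atom-sided outputs feed
  # nothing downstream; exactly these parameters are disconnected
  dead <- paste0(sprintf("mg.l%d", cfg$L_mol),
                 c(".We", ".be", ".Wv", ".bv", ".Wsv", ".Wb1", ".Wb2"))
  mg_names <- grep("^mg\\.", names(p), value = TRUE)
  for (nm in setdiff(mg_names, dead)) {
    expect_false(is.null(grads[[nm]]), label = paste("grad defined:", nm))
    expect_gt(max(abs(grads[[nm]])), 0, label = paste("grad nonzero:", nm))
  }
  for (nm in dead) {
    expect_true(is.null(grads[[nm]]) || all(grads[[nm]] == 0),
                label = paste("structurally disconnected:", nm))
  }
})
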