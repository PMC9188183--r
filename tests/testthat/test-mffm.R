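# Fusion module: adjacency normalization, gated GCN, equivariance, and
# the contrastive alignment loss.

test_that("intra-drug fusion is the elementwise sum with ablation contracts", {
  G <- matrix(c(1, 2), 1L); S <- matrix(c(3, 4), 1L)
  expect_equal(fuse_intra(G, S), matrix(c(4, 6), 1L))
  expect_equal(fuse_intra(G, G * 0), G)
  expect_error(fuse_intra(G, matrix(0, 2L, 2L)), "shape")
})

test_that("normalized adjacency matches hand-computed cases", {
  # two nodes, one edge: all degrees 2
  A2 <- matrix(c(0, 1, 1, 0), 2L)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2L, 2L))
  # isolated single node keeps its unit self-loop
  expect_equal(normalize_adjacency(matrix(0, 1L, 1L)), matrix(1, 1L, 1L))
  # three-node path
  A3 <- matrix(0, 3L, 3L); A3[1, 2] <- A3[2, 1] <- A3[2, 3] <- A3[3, 2] <- 1
  At <- normalize_adjacency(A3)
  expect_equal(At[1, 1], 1 / 2)
  expect_equal(At[1, 2], 1 / sqrt(6))
  expect_equal(At[2, 2], 1 / 3)
  expect_equal(At[2, 3], 1 / sqrt(6))
  expect_equal(At[3, 3], 1 / 2)
  expect_equal(At[1, 3], 0)
  expect_equal(At, t(At))
})

test_that("normalized adjacency is symmetric with spectral radius <= 1", {
  set.seed(8)
  for (r in 1:20) {
    n <- sample(2:12, 1)
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- sample(up, size = sample.int(length(up), 1))
    A[on] <- 1
    A <- A + t(A)
    At <- normalize_adjacency(A)
    expect_identical(At, t(At))
    expect_lte(max(abs(eigen(At, symmetric = TRUE)$values)), 1 + 1e-8)
  }
})

test_that("the gated GCN matches the straight-line oracle", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  set.seed(4)
  n <- 3L
  H <- matrix(rnorm(n * cfg$d_g), n)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3L)
  At <- normalize_adjacency(A)
  expect_equal(encode_ddi(H, A, p, cfg), oracle_gcn(H, At, p, cfg),
               tolerance = 1e-6)
  cfgu <- small_config(use_gating = FALSE, L_gcn = 1L)
  pu <- seeded_params(cfgu)
  expect_equal(encode_ddi(H, A, pu, cfgu), oracle_gcn(H, At, pu, cfgu),
               tolerance = 1e-6)
})

test_that("layer-gate endpoints skip or pass the layer", {
  cfg <- small_config(L_gcn = 1L)
  p <- seeded_params(cfg)
  set.seed(5)
  H <- matrix(rnorm(4 * cfg$d_g), 4L)
  A <- matrix(0, 4L, 4L); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  At <- normalize_adjacency(A)
  # gate forced open (+30 bias): gated path equals the ungated layer
  popen <- p
  popen$ff.r1.Wg <- p$ff.r1.Wg * 0
  popen$ff.r1.bg <- p$ff.r1.bg * 0 + 30
  cfg_ungated <- small_config(L_gcn = 1L, use_gating = FALSE)
  expect_equal(encode_ddi(H, A, popen, cfg), encode_ddi(H, A, p, cfg_ungated),
               tolerance = 1e-6)
  # gate forced shut (-30 bias): the layer is skipped entirely
  pshut <- popen
  pshut$ff.r1.bg <- p$ff.r1.bg * 0 - 30
  expect_equal(encode_ddi(H, A, pshut, cfg), H, tolerance = 1e-6)
  # zero gate weights: exact midpoint of layer output and input
  pmid <- popen
  pmid$ff.r1.bg <- p$ff.r1.bg * 0
  mid <- (encode_ddi(H, A, p, cfg_ungated) + H) / 2
  expect_equal(encode_ddi(H, A, pmid, cfg), mid, tolerance = 1e-6)
})

test_that("the DDI encoder is equivariant under drug relabeling", {
  cfg <- small_config()
  p <- seeded_params(cfg)
  set.seed(6)
  for (r in 1:5) {
    n <- 6L
    H <- matrix(rnorm(n * cfg$d_g), n)
    A <- matrix(0, n, n)
    on <- sample(which(upper.tri(A)), 7)
    A[on] <- 1; A <- A + t(A)
    perm <- sample(n)
    Z <- encode_ddi(H, A, p, cfg)
    Zp <- encode_ddi(H[perm, ], A[perm, perm], p, cfg)
    expect_equal(Zp, Z[perm, ], tolerance = 1e-6)
  }
})

test_that("no edges degenerate the GCN to per-node transforms", {
  cfg <- small_config(use_gating = FALSE, L_gcn = 1L)
  p <- seeded_params(cfg)
  H <- matrix(rnorm(3 * cfg$d_g), 3L)
  Z <- encode_ddi(H, matrix(0, 3L, 3L), p, cfg)
  expect_equal(Z, pmax(H %*% p$ff.r1.Wu, 0), tolerance = 1e-12)
})

test_that("contrastive loss matches closed-form evaluation and the oracle", {
  # all-zero representations: -ln(sigma(0)) - ln(sigma(1)) per drug
  H <- matrix(0, 3L, 4L); Z <- matrix(0, 3L, 4L)
  A <- matrix(0, 3L, 3L); A[1, 2] <- A[2, 1] <- 1
  val <- contrastive_loss(H, Z, A, seed = 1)
  expect_equal(val, -log(0.5) - log(1 / (1 + exp(-1))), tolerance = 1e-10)
  expect_equal(val, 1.0064, tolerance = 1e-4)

  set.seed(10)
  H <- matrix(rnorm(12), 3L); Z <- matrix(rnorm(12), 3L)
  neg_idx <- mffgnn:::with_seed(2, mffgnn:::sample_corruptions(A))
  ctx <- mffgnn:::fwd_ctx(list(), small_config(), training = FALSE)
  node <- mffgnn:::contrastive_loss_node(ctx, mffgnn:::ad_const(ctx$tape, H),
                                         mffgnn:::ad_const(ctx$tape, Z), neg_idx)
  expect_equal(as.numeric(node$value), oracle_contrastive(H, Z, neg_idx),
               tolerance = 1e-10)
  expect_gte(as.numeric(node$value), 0)
})

test_that("contrastive loss saturates and decreases in the positive score", {
  # strong agreement + strong corruption disagreement drives the loss to 0
  H <- rbind(c(50, 0), c(0, 50))
  Z <- rbind(c(1, -1), c(-1, 1))
  A <- matrix(0, 2L, 2L)
  v <- contrastive_loss(H, Z, A, seed = 1)
  expect_lt(v, 1e-8)
  expect_gte(v, 0)
  # monotone decrease along a sweep of the positive dot product
  sweep_vals <- vapply(seq(-3, 3, by = 0.5), function(s) {
    Hs <- matrix(s, 2L, 1L); Zs <- matrix(1, 2L, 1L)
    neg <- c(2L, 1L)
    oracle_contrastive(Hs, Zs, neg)
  }, numeric(1))
  # the negative term rises with s here, so use the pure positive term
  pos_term <- vapply(seq(-3, 3, by = 0.5), function(s) {
    -log(1 / (1 + exp(-s)))
  }, numeric(1))
  expect_true(all(diff(pos_term) < 0))
  # a drug adjacent to all others skips its negative term with a message
  Afull <- matrix(1, 2L, 2L) - diag(2)
  expect_message(contrastive_loss(matrix(0, 2L, 2L), matrix(0, 2L, 2L),
                                  Afull, seed = 3), "skipped")
})
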