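# mffgnn

Drug–drug interaction (DDI) prediction by multi-type feature fusion with
graph neural networks, in pure R.

Unexpected interactions between co-administered drugs are a major source
of adverse events, and screening pairs experimentally does not scale.
Treating known interactions as edges of a network over drugs turns the
screening problem into transductive link prediction.  This package
implements an end-to-end model that fuses the three descriptions a drug
comes with:

* **M** — its molecular graph, encoded by a message-passing network
  interleaved with a *graph warp unit*: a supernode `g` connected to
  every atom, a K-head attention transmitter between atoms and
  supernode, sigmoid warp gates, and GRU state updates;
* **S** — its SMILES string, tokenized and encoded by a bidirectional
  GRU with per-timestep combination
  `s_t = W_t s⃗_t + V_t s⃖_t + b_t`;
* **I** — its position in the DDI network: the intra-drug features
  `H = G ⊕ S` seed a multi-layer GCN over the normalized adjacency
  `Ã = K̂^(-1/2)(A + I)K̂^(-1/2)`, each layer blended with its input
  through an elementwise gate against over-smoothing.

A pair `(i, j)` is scored as `ŷ_ij = σ(MLP(z_i ⊙ z_j))` and training
minimizes `L = L_r + α·L_c`: binary cross-entropy over labeled pairs
plus a contrastive term aligning each drug's intra-drug vector with its
fused network vector against sampled non-neighbour corruptions.
Ablation switches remove the warp unit (`-GWU`), the layer gates
(`-Gating`), the contrastive term (`-Contrastive`), or restrict the
feature set to any non-empty subset of `{S, M, I}`.

All tensor operations run on a small reverse-mode automatic
differentiation engine written in base R (`R/autodiff.R`), validated
against finite differences; no Python or compiled deep-learning runtime
is required.

## Worked example

```r
library(mffgnn)

# 20 drugs in two planted communities: within-community interaction
# probability 0.6, across 0.05, drug-like SMILES from a built-in library
d <- generate_synthetic(n_drugs = 20, n_communities = 2, p_in = 0.6,
                        p_out = 0.05, seed = 1)
d
#> Interaction dataset: 20 drugs, 61 positive DDI links

cfg <- mffgnn_config(d_h = 32, d_g = 32, L_s = 60, lr0 = 0.02,
                     lr_decay = 0.98, epochs = 250, patience = 60)
fit <- mffgnn(d, cfg)   # 80/20 split, 20% of train held out for validation
fit
#> Multi-type feature-fusion DDI model
#>   20 drugs, 39 training positives; features {S,M,I}
#>   trained 65 epoch(s); best validation AUROC 1.0000 at epoch 5

evaluate_model(fit, partition = "test")
#> AUROC 0.8125  AUPRC 0.8281  F1 0.7857  (12 pos / 12 neg, thr 0.50)

head(predict(fit), 3)
#>   drug_id_a drug_id_b     score label
#> 1      D003      D007 0.5896646     1
#> 2      D004      D005 0.5362025     1
#> 3      D002      D010 0.5896215     1
```

The test AUROC of 0.81 is essentially the information ceiling of these
synthetic conditions: held-out edges depend on the training graph only
through the community memberships, so even a perfect model is capped by
the cross-community noise edges and the within-community negatives (see
the methods vignette).

The fitted object supports `print`, `summary`, `coef`, `predict`,
`plot` (training curves), `residuals` and `simulate`.  Checkpoints
round-trip with `save_mffgnn()` / `load_mffgnn()`; `run_repeats()`,
`run_sweep()` and `cross_dataset_eval()` cover the repeat, parameter
sweep and transfer protocols.  A command-line interface with
`simulate`, `train`, `predict`, `evaluate` and `crossval` subcommands
is installed at `system.file("cli", "mffgnn.R", package = "mffgnn")`.

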