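---
title: "Multi-type feature fusion for DDI link prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-type feature fusion for DDI link prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mffgnn)
```

## The problem

A drug–drug interaction (DDI) network is an undirected graph whose nodes
are drugs and whose edges record known interactions; the prediction task
is transductive link prediction: all drugs are visible during training,
a subset of edges is labeled for supervision, and the model must rank
held-out drug pairs by their probability of interacting.  Each drug
carries two intrinsic descriptions — its molecular graph (atoms and
bonds) and its SMILES string — in addition to its position in the
interaction network.  The model fuses all three.

## Architecture

**Molecular-graph encoder.**  Atoms and bonds are featurized (element,
formal charge, aromaticity, hybridization, chirality tag, degree; bond
type, ring membership, conjugation) and projected into $\mathbb{R}^{d_h}$
with a ReLU layer.  Each layer then runs a graph interaction network
update — bond states are updated from the concatenation
$(e_{ij} \,\|\, v_i \,\|\, v_j)$, atom states from their incoming bond
sum — interleaved with a *graph warp unit*: a supernode $g$ connected to
every atom carries a global molecule state, initialized as
$g^{(0)} = \sum_i v_i^{(0)}$.  A transmitter moves information in both
directions: $K$-head attention ($\alpha_{v,i}^{(k)}$ softmax-normalized
over atoms, with per-head scores
$\tanh(W_{a1} v_i) \odot \tanh(W_{a2} g)$) aggregates atoms into the
supernode message, and a linear-tanh map sends the supernode back to the
atoms.  Warp gates fuse each side by sigmoid-gated convex interpolation,
and two shared GRU cells (one for atoms, one for the supernode) perform
the state transition.  The drug vector is a linear projection of the
final supernode state.

**Sequence encoder.**  SMILES strings are tokenized (bracket atoms and
two-letter elements as single tokens, every other character on its own),
mapped through a trainable embedding table (padding id 0 is frozen at
zero), and encoded by a bidirectional GRU.  Per timestep the directional
states combine linearly, $s_t = W_t \vec{s}_t + V_t \overleftarrow{s}_t
+ b_t$; the masked mean over valid positions feeds a fully connected
readout.

**Fusion over the DDI network.**  The intra-drug matrix is the
elementwise sum $H = G \oplus S$ (plus a trainable per-drug embedding
when identity features are enabled).  A GCN propagates it over the
symmetrically normalized training adjacency
$\tilde A = \hat K^{-1/2}(A + I)\hat K^{-1/2}$; each layer's output is
blended with its input through an elementwise sigmoid gate
(highway-style) to counter over-smoothing.  A contrastive loss aligns
each drug's intra-drug vector $h_i$ with its fused vector $z_i$ (dot
product discriminator) against one sampled non-neighbour corruption per
drug, resampled every epoch.

**Scorer and objective.**  A pair is represented by $z_i \odot z_j$
(symmetric by construction) and scored by a two-layer MLP with a sigmoid
output.  Training minimizes
$\mathcal{L} = \mathcal{L}_r + \alpha\, \mathcal{L}_c$, the sum of the
binary cross-entropy over labeled pairs and $\alpha$ times the
contrastive term, with Adam, Xavier initialization, and an exponential
learning-rate schedule $lr_e = lr_0 \cdot \gamma^{e}$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d_h` | 256 | atom/bond/token state width |
| `d_g` | 256 | drug representation width |
| `K` | 2 | transmitter attention heads |
| `L_mol` | 2 | molecular-encoder layers |
| `L_gcn` | 3 | fusion GCN layers |
| `L_s` | 150 | fixed token-sequence length |
| `dropout` | 0.3 | dropout on intermediate states |
| `lr0`, `lr_decay` | 1e-4, 0.96 | learning-rate schedule |
| `alpha` | 0.9 | contrastive weight |

The defaults mirror the reference experimental setup for the public DDI
datasets (hundreds to thousands of drugs).  They are *not* good choices
for the tiny synthetic problems used in this package's tests: at 20
drugs and ~60 links a 256-dimensional model at `lr0 = 1e-4` is grossly
under-trained within any reasonable epoch budget.  The desk-scale
configuration used throughout the test suite and the acceptance script
is `d_h = d_g = 32`, `L_s = 60`, `lr0 = 0.02`, `lr_decay = 0.98`, at
most 250 epochs with early stopping (patience 60 on validation AUROC,
evaluated every epoch).  Training on those sizes takes seconds to tens
of seconds per fit on one CPU.

## The synthetic generator

`generate_synthetic()` emulates the structure of the public DDI corpora
without downloads: drugs receive valid drug-like SMILES from a built-in
scaffold library (optionally decorated with a short substituent prefix),
and interactions follow a planted-partition model — within-community
probability `p_in`, between-community `p_out` — so community membership
is a learnable link signal.  What it deliberately does **not** emulate:
any dependence of the link pattern on chemistry (SMILES are assigned
independently of communities), realistic degree heterogeneity, and
multi-type interaction semantics.  Passing tests on this generator
therefore demonstrate that the pipeline can extract a genuine
topological signal end to end, not that chemistry features carry signal
on real data.

**A ceiling worth knowing.**  In the planted-partition model, held-out
edges are conditionally independent of the training edges given the
community memberships.  The best possible scorer is therefore the
same-community indicator, and its held-out AUROC is bounded well below 1
because (i) a fraction of true test edges are cross-community noise
(`p_out > 0`) and (ii) a fraction of sampled negatives are
within-community pairs that tie with the positives.  At the study
conditions used in the signal-recovery checks (20 drugs, two
communities, `p_in = 0.6`, `p_out = 0.05`, 12 positive + 12 negative
test pairs) this ceiling sits in the low 0.8s on typical splits, with
substantial split-to-split variance.  The fitted model tracks this
ceiling; apparent "failures" to reach high AUROC on some splits are
information-theoretic, not optimization artifacts.  For the same reason
the shuffled-label control is estimated as the *mean* AUROC over 200
label permutations — a single permutation of 24 labels has a standard
deviation near 0.1, which would dominate the quantity being measured.

## Design choices where the design was open

* **Readout of the molecular encoder:** linear projection of the final
  supernode state — the supernode is the architecture's designated
  global carrier.  The `-GWU` ablation (no supernode path) mean-pools
  the final atom states instead.  A consequence of the supernode
  readout is that the last layer's atom-sided parameters (edge/node
  update, supernode-to-atom projection, atom warp gate) are
  structurally downstream-disconnected and receive zero gradient; this
  is asserted, not hidden, in the test suite.
* **Neighbour aggregation** in the node update runs over incoming
  directed edges; since every bond is stored in both directions this
  equals undirected aggregation.
* **Gate algebra:** the supernode warp gate uses its own gating
  coefficient (computed from $\tilde g$ and the transmitted atom
  message) in its interpolation; the per-layer GCN gate reads the
  *previous* layer's state and blends the pre-gate layer output with
  that state — the only readings that define functions.
* **Sequence pooling:** masked mean over valid timesteps before the
  readout, making drug vectors invariant to padding length.  Neither
  the direction combination nor the readouts carry extra
  nonlinearities.
* **Tokenizer:** SMILES contain no whitespace, so "splitting by atoms"
  is realized as a deterministic regex pass; non-atom symbols (ring
  digits, parentheses, bond characters) are kept as tokens so the
  recurrent encoder sees the full sequence syntax.  Embeddings are
  trained end to end; a hook loads a user-supplied token-vector file.
* **Negative sampling:** supervised negatives are drawn once at split
  time, uniformly and without replacement across partitions (a flag
  enables per-epoch resampling); contrastive corruptions are resampled
  every epoch.  Message passing uses the training-positive adjacency
  only, so held-out edges never leak into $\tilde A$.
* **Identity features:** the "I" feature set is a trainable per-drug
  embedding, the standard featureless-GCN convention.
* **Out-of-vocabulary tokens** at cross-dataset time map to a dedicated
  trainable unknown embedding.

## Numerical choices

Predictions are clamped to $[10^{-7}, 1 - 10^{-7}]$ before the log loss;
sigmoid outputs inside the contrastive term are clamped at $10^{-12}$.
Softmax attention is max-shifted per molecule.  Xavier-uniform
initialization everywhere, zero biases, zero and frozen padding
embedding row.  All straight-line oracle comparisons in the tests use an
absolute tolerance of $10^{-6}$ in double precision (permutation
invariance $10^{-5}$, accumulated over layers).  Degenerate inputs are
defined, not special-cased: single-atom molecules have an empty
neighbour sum, isolated drugs keep a unit self-loop in $\tilde A$, and a
drug adjacent to every other drug skips its contrastive corruption term
(logged).  Everything is driven by one integer seed per fit —
initialization, splits, dropout masks and corruption sampling — so two
runs with the same configuration produce bitwise-identical loss
trajectories.

## Known limitations

The SMILES parser covers the organic subset, bracket atoms, rings
(including `%nn`), branches and aromatic notation, but not disconnected
salts, reaction syntax or full valence checking; records it cannot read
are dropped with a message, mirroring the upstream datasets' own
filtering.  Hybridization and conjugation flags follow declared rules
rather than a toolkit's perception.  Training is full-graph per epoch,
appropriate for the transductive sizes in scope; the autodiff engine is
plain R and favours clarity over large-scale throughput.  Multi-type
(event-level) DDI prediction is out of scope.
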