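# Shared fixtures: tiny deterministic datasets and configurations.

tiny_smiles <- c("CCO", "c1ccccc1", "CC(=O)O", "CCN", "C1CCCCC1",
                 "COc1ccccc1", "CC(N)C(=O)O", "Oc1ccncc1")

tiny_dataset <- function(n = 6L, edges = NULL) {
  drugs <- data.frame(drug_id = paste0("d", seq_len(n)),
                      smiles = tiny_smiles[seq_len(n)],
                      stringsAsFactors = FALSE)
  if (is.null(edges)) {
    edges <- data.frame(drug_id_a = c("d1", "d1", "d2", "d3", "d4"),
                        drug_id_b = c("d2", "d3", "d3", "d4", "d5"),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$drug_id_a %in% drugs$drug_id &
                     edges$drug_id_b %in% drugs$drug_id, ]
  }
  suppressMessages(make_interaction_dataset(drugs, edges))
}

small_config <- function(...) {
  base <- list(d_h = 6L, d_g = 5L, K = 2L, L_mol = 2L, L_gcn = 2L,
               L_s = 20L, dropout = 0, epochs = 2L, lr0 = 0.01, seed = 1L)
  do.call(mffgnn_config, utils::modifyList(base, list(...)))
}

# Parameters for a standalone config, seeded.
seeded_params <- function(config, vocab_size = 30L, n_drugs = 6L,
                          seed = 11L) {
  mffgnn:::with_seed(seed, mffgnn:::init_params(config, atom_dim = 31L,
                                                bond_dim = 6L,
                                                vocab_size = vocab_size,
                                                n_drugs = n_drugs))
}

scaled_config <- function(...) {
  base <- list(d_h = 32L, d_g = 32L, L_s = 60L, lr0 = 0.02,
               lr_decay = 0.98, epochs = 250L, patience = 60L,
               eval_every = 1L)
  do.call(mffgnn_config, utils::modifyList(base, list(...)))
}

# Mean AUROC over label permutations: the permutation-null control.
shuffled_control <- function(scores, labels, n_perm = 200L, seed = 7L) {
  mffgnn:::with_seed(seed,
    mean(replicate(n_perm, auroc(scores, sample(labels)))))
}
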