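# Interaction datasets: drug records (SMILES -> molecular graph + token
# sequence), the positive DDI edge set and its adjacency matrix,
# transductive splits with matched negatives, and the planted-partition
# synthetic generator.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Build an interaction dataset from drug and edge tables
#'
#' Parses every SMILES into a molecular graph and token list.  Drugs whose
#' SMILES cannot be parsed are dropped (with a message), and edges touching
#' dropped drugs are removed.  Duplicate drug ids, self-interaction edges,
#' duplicate (or mirrored-duplicate) edges, and edges referencing unknown
#' drugs are errors.
#'
#' @param drugs data frame with columns `drug_id`, `smiles`.
#' @param edges data frame with columns `drug_id_a`, `drug_id_b`
#'   (undirected positive interactions).
#' @return object of class `interaction_dataset`: list with `drugs`
#'   (data frame of kept drugs), `graphs` (list of [parse_smiles()]
#'   results), `tokens` (list of token vectors), `positive_pairs`
#'   (m x 2 integer matrix of drug indices, first column smaller), and
#'   `adjacency` (symmetric 0/1 matrix, zero diagonal).
#' @export
make_interaction_dataset <- function(drugs, edges) {
  req <- c("drug_id", "smiles")
  if (!all(req %in% names(drugs))) {
    stop("drug table must have columns: ", paste(req, collapse = ", "))
  }
  req_e <- c("drug_id_a", "drug_id_b")
  if (!all(req_e %in% names(edges))) {
    stop("edge list must have columns: ", paste(req_e, collapse = ", "))
  }
  drugs$drug_id <- as.character(drugs$drug_id)
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug ids: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]), collapse = ", "))
  }
  ea <- as.character(edges$drug_id_a)
  eb <- as.character(edges$drug_id_b)
  if (any(ea == eb)) stop("self-interaction edges are not allowed")
  unknown <- setdiff(c(ea, eb), drugs$drug_id)
  if (length(unknown) > 0L) {
    stop("edges reference unknown drug ids: ", paste(unknown, collapse = ", "))
  }
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  if (anyDuplicated(key)) stop("duplicate (or mirrored) edges in edge list")

  graphs <- vector("list", nrow(drugs))
  tokens <- vector("list", nrow(drugs))
  ok <- logical(nrow(drugs))
  for (i in seq_len(nrow(drugs))) {
    res <- tryCatch(parse_smiles(drugs$smiles[i]), error = function(e) e)
    if (inherits(res, "error")) {
      message("dropping drug ", drugs$drug_id[i], ": ", conditionMessage(res))
    } else {
      graphs[[i]] <- res
      tokens[[i]] <- tokenize_smiles(drugs$smiles[i])
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no parsable drugs in the table")
  dropped <- drugs$drug_id[!ok]
  drugs <- drugs[ok, , drop = FALSE]
  rownames(drugs) <- NULL
  graphs <- graphs[ok]
  tokens <- tokens[ok]

  keep_edge <- !(ea %in% dropped) & !(eb %in% dropped)
  if (sum(!keep_edge) > 0L) {
    message("dropping ", sum(!keep_edge), " edge(s) touching unparsable drugs")
  }
  ea <- ea[keep_edge]; eb <- eb[keep_edge]

  n <- nrow(drugs)
  ia <- match(ea, drugs$drug_id)
  ib <- match(eb, drugs$drug_id)
  pairs <- cbind(pmin(ia, ib), pmax(ia, ib))
  adjacency <- matrix(0, n, n)
  if (nrow(pairs) > 0L) {
    adjacency[pairs] <- 1
    adjacency[pairs[, c(2L, 1L), drop = FALSE]] <- 1
  }
  dimnames(adjacency) <- list(drugs$drug_id, drugs$drug_id)

  structure(list(drugs = drugs, graphs = graphs, tokens = tokens,
                 positive_pairs = pairs, adjacency = adjacency),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("Interaction dataset: %d drugs, %d positive DDI links\n",
              nrow(x$drugs), nrow(x$positive_pairs)))
  invisible(x)
}

#' Read an interaction dataset from disk
#'
#' @param drug_table_path CSV/TSV with header `drug_id,smiles`.
#' @param edge_list_path CSV/TSV with header `drug_id_a,drug_id_b`.
#' @return an `interaction_dataset`; see [make_interaction_dataset()].
#' @export
read_dataset <- function(drug_table_path, edge_list_path) {
  read_any <- function(path) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
  }
  make_interaction_dataset(read_any(drug_table_path),
                           read_any(edge_list_path))
}

#' Write an interaction dataset to a directory
#'
#' Emits `drugs.csv` (`drug_id,smiles`) and `edges.csv`
#' (`drug_id_a,drug_id_b`).
#'
#' @param dataset an `interaction_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$drugs[, c("drug_id", "smiles")],
                   file.path(dir, "drugs.csv"), row.names = FALSE)
  p <- dataset$positive_pairs
  utils::write.csv(data.frame(drug_id_a = dataset$drugs$drug_id[p[, 1L]],
                              drug_id_b = dataset$drugs$drug_id[p[, 2L]]),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}

all_nonedges <- function(adjacency) {
  n <- nrow(adjacency)
  idx <- which(upper.tri(adjacency) & adjacency == 0, arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}

#' Split positives into train/validation/test with matched negatives
#'
#' Positives are randomly partitioned 64%/16%/20% (i.e. 80% train with 20%
#' of the training portion held out for validation, 20% test).  Each
#' partition receives an equal number of negatives sampled uniformly
#' without replacement from the non-adjacent pairs, so no negative is a
#' positive and none is duplicated anywhere in the bundle.
#'
#' @param dataset an `interaction_dataset` with at least 5 positives.
#' @param seed integer seed; the split is reproducible and does not
#'   disturb the caller's RNG state.
#' @return object of class `split_bundle`: `train_pos`, `val_pos`,
#'   `test_pos`, `train_neg`, `val_neg`, `test_neg` (each an m x 2 index
#'   matrix) and `seed`.
#' @export
make_splits <- function(dataset, seed) {
  pos <- dataset$positive_pairs
  m <- nrow(pos)
  if (m < 5L) stop("need at least 5 positive pairs to split")
  with_seed(seed, {
    perm <- sample.int(m)
    n_test <- round(0.20 * m)
    n_val <- round(0.16 * m)
    n_train <- m - n_test - n_val
    if (min(n_test, n_val, n_train) < 1L) stop("too few positives to split")
    train_pos <- pos[perm[seq_len(n_train)], , drop = FALSE]
    val_pos <- pos[perm[n_train + seq_len(n_val)], , drop = FALSE]
    test_pos <- pos[perm[n_train + n_val + seq_len(n_test)], , drop = FALSE]
    nonedges <- all_nonedges(dataset$adjacency)
    if (nrow(nonedges) < m) {
      stop("interaction graph too dense to sample matched negatives")
    }
    neg_perm <- sample.int(nrow(nonedges), m)
    train_neg <- nonedges[neg_perm[seq_len(n_train)], , drop = FALSE]
    val_neg <- nonedges[neg_perm[n_train + seq_len(n_val)], , drop = FALSE]
    test_neg <- nonedges[neg_perm[n_train + n_val + seq_len(n_test)], ,
                         drop = FALSE]
    structure(list(train_pos = unname(train_pos), val_pos = unname(val_pos),
                   test_pos = unname(test_pos), train_neg = unname(train_neg),
                   val_neg = unname(val_neg), test_neg = unname(test_neg),
                   seed = seed), class = "split_bundle")
  })
}

#' @export
print.split_bundle <- function(x, ...) {
  cat(sprintf(
    "Split bundle (seed %d): %d/%d/%d positives, matched negatives\n",
    x$seed, nrow(x$train_pos), nrow(x$val_pos), nrow(x$test_pos)))
  invisible(x)
}

#' Serialize a split bundle to CSV
#'
#' Columns `drug_id_a,drug_id_b,label,partition`.
#'
#' @param bundle a `split_bundle`.
#' @param dataset the `interaction_dataset` the bundle indexes into.
#' @param path output CSV path.
#' @export
write_splits <- function(bundle, dataset, path) {
  rows <- list()
  for (part in c("train", "val", "test")) {
    for (lab in c(1, 0)) {
      p <- bundle[[paste0(part, if (lab == 1) "_pos" else "_neg")]]
      if (nrow(p) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id_a = dataset$drugs$drug_id[p[, 1L]],
        drug_id_b = dataset$drugs$drug_id[p[, 2L]],
        label = lab, partition = part)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a split bundle from CSV
#'
#' @param path CSV written by [write_splits()].
#' @param dataset the matching `interaction_dataset`.
#' @return a `split_bundle` (seed recorded as `NA`).
#' @export
read_splits <- function(path, dataset) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list(seed = NA_integer_)
  for (part in c("train", "val", "test")) {
    for (lab in c(1, 0)) {
      sel <- df$partition == part & df$label == lab
      ia <- match(df$drug_id_a[sel], dataset$drugs$drug_id)
      ib <- match(df$drug_id_b[sel], dataset$drugs$drug_id)
      if (anyNA(ia) || anyNA(ib)) stop("splits reference unknown drug ids")
      out[[paste0(part, if (lab == 1) "_pos" else "_neg")]] <-
        cbind(pmin(ia, ib), pmax(ia, ib))
    }
  }
  structure(out, class = "split_bundle")
}

# Drug-like scaffold library for the synthetic generator.  `decoratable`
# marks scaffolds whose first atom can accept one more substituent, so a
# short alkyl/ether/amine prefix stays chemically valid.
synthetic_smiles_library <- function() {
  data.frame(stringsAsFactors = FALSE, rbind(
    c("CCO", TRUE), c("CC(=O)O", TRUE), c("CC(=O)Oc1ccccc1C(=O)O", TRUE),
    c("CC(C)Cc1ccc(cc1)C(C)C(=O)O", TRUE), c("CC(=O)Nc1ccc(O)cc1", TRUE),
    c("Cn1cnc2c1c(=O)n(C)c(=O)n2C", TRUE), c("CN1CCCC1c1cccnc1", TRUE),
    c("c1ccccc1", TRUE), c("c1ccncc1", TRUE), c("c1ccc2ccccc2c1", TRUE),
    c("C1CCCCC1", TRUE), c("C1CCNCC1", TRUE), c("OCC1OC(O)C(O)C(O)C1O", FALSE),
    c("NC(=O)c1ccccc1", FALSE), c("Nc1ccccc1", FALSE), c("Oc1ccccc1", FALSE),
    c("Clc1ccccc1", FALSE), c("CC(N)C(=O)O", TRUE),
    c("NCCc1ccc(O)c(O)c1", FALSE), c("CN(C)CCc1ccccc1", TRUE),
    c("CC(=O)NCCc1c[nH]c2ccccc12", TRUE), c("O=C(O)c1ccccc1O", FALSE),
    c("CCN(CC)CC", TRUE), c("CCOC(=O)C", TRUE), c("CSCCC(N)C(=O)O", TRUE),
    c("NC(CS)C(=O)O", FALSE), c("NS(=O)(=O)c1ccccc1", FALSE),
    c("c1cncnc1", TRUE), c("c1c[nH]cn1", TRUE), c("c1ccoc1", TRUE),
    c("c1ccsc1", TRUE), c("c1cc[nH]c1", TRUE), c("FC(F)(F)c1ccccc1", FALSE),
    c("N#Cc1ccccc1", FALSE), c("CC#N", TRUE), c("C=CC=C", TRUE),
    c("COc1ccccc1", TRUE), c("CN1CCN(C)CC1", TRUE), c("O=C1CCCCC1", FALSE),
    c("CC(C)(C)c1ccccc1", TRUE), c("Brc1ccccc1", FALSE), c("Ic1ccccc1", FALSE),
    c("OC(=O)CCC(=O)O", FALSE), c("NCCCC(N)C(=O)O", FALSE),
    c("OC(=O)C1CCCN1", FALSE), c("[O-][N+](=O)c1ccccc1", FALSE),
    c("CC1=CC(=O)CC(C)(C)C1", TRUE), c("c1ccc(cc1)c1ccccc1", TRUE),
    c("OCCN1CCOCC1", FALSE), c("CC(C)NCC(O)COc1ccccc1", TRUE)
  )) -> df
  names(df) <- c("smiles", "decoratable")
  df$decoratable <- as.logical(df$decoratable)
  df
}

#' Generate a synthetic DDI dataset with planted community structure
#'
#' Drugs receive valid small-molecule SMILES drawn from a built-in
#' drug-like scaffold library, optionally decorated with a short
#' substituent prefix.  Interactions follow a planted-partition model:
#' drugs are assigned to `n_communities` (near-)equal contiguous
#' communities, and each unordered pair is a positive link with
#' probability `p_in` within a community and `p_out` across communities,
#' so community membership is a learnable link signal.
#'
#' @param n_drugs number of drugs (`>= 2`).
#' @param n_communities number of planted communities.
#' @param p_in,p_out within/between-community link probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer seed; output is fully reproducible and the
#'   caller's RNG state is untouched.
#' @return an `interaction_dataset` with an extra `community` integer
#'   vector attached.
#' @examples
#' d <- generate_synthetic(12, 2, 0.8, 0.05, seed = 1)
#' d$community
#' @export
generate_synthetic <- function(n_drugs, n_communities, p_in, p_out, seed) {
  stopifnot(n_drugs >= 2L, n_communities >= 1L,
            p_out >= 0, p_in <= 1, p_out < p_in)
  lib <- synthetic_smiles_library()
  decorations <- c("C", "CC", "CCC", "OC", "NC")
  with_seed(seed, {
    base <- sample.int(nrow(lib), n_drugs, replace = TRUE)
    smiles <- vapply(base, function(b) {
      s <- lib$smiles[b]
      if (lib$decoratable[b] && stats::runif(1) < 0.5) {
        s <- paste0(sample(decorations, 1L), s)
      }
      s
    }, character(1L))
    drugs <- data.frame(drug_id = sprintf("D%03d", seq_len(n_drugs)),
                        smiles = smiles, stringsAsFactors = FALSE)
    community <- sort(rep_len(seq_len(n_communities), n_drugs))
    ea <- character(0); eb <- character(0)
    for (i in seq_len(n_drugs - 1L)) {
      for (j in seq.int(i + 1L, n_drugs)) {
        p <- if (community[i] == community[j]) p_in else p_out
        if (stats::runif(1) < p) {
          ea <- c(ea, drugs$drug_id[i])
          eb <- c(eb, drugs$drug_id[j])
        }
      }
    }
    dataset <- make_interaction_dataset(
      drugs, data.frame(drug_id_a = ea, drug_id_b = eb,
                        stringsAsFactors = FALSE))
    dataset$community <- community[match(dataset$drugs$drug_id,
                                         drugs$drug_id)]
    dataset
  })
}
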