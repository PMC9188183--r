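# SMILES tokenization, a restricted SMILES parser, and the frozen
# atom/bond featurization schema.
#
# The parser covers the organic subset (B C N O P S F Cl Br I), aromatic
# lowercase atoms, bracket atoms with isotope/chirality/H-count/charge,
# ring closures (including %nn), branches and explicit bond symbols.
# Stereo bond symbols / and \ are read as single bonds; disconnected
# structures (".") are rejected, as are strings the grammar cannot read --
# at dataset level such records are dropped.

ATOM_ELEMENTS <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
ORGANIC_AROMATIC <- c("b", "c", "n", "o", "p", "s")

#' Tokenize a SMILES string
#'
#' Deterministic left-to-right tokenization: bracket atoms (`[...]`) and the
#' two-letter organic-subset elements `Cl`/`Br` are single tokens; every
#' other character (ring digits, parentheses, bond symbols, `%`) is its own
#' token.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenize_smiles("CC(Cl)Br")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  # bracket balance: SMILES brackets never nest
  depth <- 0L
  for (ch in strsplit(smiles, "", fixed = TRUE)[[1L]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (depth < 0L || depth > 1L) {
      stop("unbalanced brackets in SMILES: ", smiles)
    }
  }
  if (depth != 0L) stop("unbalanced brackets in SMILES: ", smiles)
  m <- gregexpr("\\[[^][]*\\]|Cl|Br|.", smiles)[[1L]]
  regmatches(smiles, list(m))[[1L]]
}

parse_bracket_atom <- function(tok) {
  m <- regmatches(tok, regexec(
    "^\\[([0-9]*)([A-Za-z][a-z]?)(@@|@)?(H[0-9]*)?([+-][0-9]+|\\++|-+)?(:[0-9]+)?\\]$",
    tok))[[1L]]
  if (length(m) == 0L) stop("cannot read bracket atom: ", tok)
  sym <- m[3L]
  chir <- m[4L]
  chg <- m[5L + 1L]  # charge group is the 6th capture -> index 6
  charge <- 0L
  if (nzchar(chg)) {
    if (grepl("^[+-][0-9]+$", chg)) {
      charge <- as.integer(chg)
    } else {
      charge <- nchar(chg) * (if (substr(chg, 1L, 1L) == "+") 1L else -1L)
    }
  }
  list(symbol = sym, charge = charge,
       chirality = if (!nzchar(chir)) 0L else if (chir == "@") 1L else 2L)
}

# Internal parse of the token stream into atoms and undirected bonds.
parse_smiles_tokens <- function(tokens, smiles) {
  atoms <- list()   # each: element, aromatic, charge, chirality
  bonds <- list()   # each: a, b, code in c("s","d","t","a")
  prev <- 0L
  stack <- integer(0)
  pending <- NULL
  rings <- list()
  bond_codes <- c("-" = "s", "=" = "d", "#" = "t", ":" = "a",
                  "/" = "s", "\\" = "s")

  add_atom <- function(symbol, aromatic, charge, chirality) {
    elem <- paste0(toupper(substr(symbol, 1L, 1L)),
                   substring(symbol, 2L))
    atoms[[length(atoms) + 1L]] <<- list(element = elem, aromatic = aromatic,
                                         charge = charge,
                                         chirality = chirality)
    idx <- length(atoms)
    if (prev > 0L) {
      code <- pending
      if (is.null(code)) {
        code <- if (atoms[[prev]]$aromatic && aromatic) "a" else "s"
      }
      bonds[[length(bonds) + 1L]] <<- list(a = prev, b = idx, code = code)
    }
    pending <<- NULL
    prev <<- idx
  }

  close_ring <- function(key) {
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, code = pending)
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      code <- pending
      if (is.null(code)) code <- open$code
      if (is.null(code)) {
        code <- if (atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic)
          "a" else "s"
      }
      if (open$atom == prev) stop("ring closure to self in SMILES: ", smiles)
      bonds[[length(bonds) + 1L]] <<- list(a = open$atom, b = prev,
                                           code = code)
    }
    pending <<- NULL
  }

  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok %in% ATOM_ELEMENTS) {
      add_atom(tok, FALSE, 0L, 0L)
    } else if (tok %in% ORGANIC_AROMATIC) {
      add_atom(tok, TRUE, 0L, 0L)
    } else if (startsWith(tok, "[")) {
      at <- parse_bracket_atom(tok)
      aromatic <- at$symbol %in% ORGANIC_AROMATIC ||
        at$symbol == tolower(at$symbol) && nchar(at$symbol) <= 2L &&
        grepl("^[a-z]", at$symbol)
      add_atom(at$symbol, aromatic, at$charge, at$chirality)
    } else if (grepl("^[0-9]$", tok)) {
      if (prev == 0L) stop("ring digit before any atom in SMILES: ", smiles)
      close_ring(tok)
    } else if (tok == "%") {
      if (i + 2L > length(tokens) ||
          !grepl("^[0-9]$", tokens[i + 1L]) ||
          !grepl("^[0-9]$", tokens[i + 2L])) {
        stop("bad %nn ring closure in SMILES: ", smiles)
      }
      close_ring(paste0(tokens[i + 1L], tokens[i + 2L]))
      i <- i + 2L
    } else if (tok == "(") {
      if (prev == 0L) stop("branch before any atom in SMILES: ", smiles)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced parentheses in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% names(bond_codes)) {
      pending <- unname(bond_codes[tok])
    } else if (tok == ".") {
      stop("disconnected SMILES not supported: ", smiles)
    } else {
      stop("unrecognized SMILES token '", tok, "' in: ", smiles)
    }
    i <- i + 1L
  }
  if (length(stack) > 0L) stop("unbalanced parentheses in SMILES: ", smiles)
  if (length(rings) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(atoms) == 0L) stop("no atoms in SMILES: ", smiles)
  list(atoms = atoms, bonds = bonds)
}

# Bond is in a ring iff its endpoints stay connected after removing it.
ring_bond_flags <- function(n, bonds) {
  if (length(bonds) == 0L) return(logical(0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_along(bonds)) {
    b <- bonds[[k]]
    adj[[b$a]] <- c(adj[[b$a]], k)
    adj[[b$b]] <- c(adj[[b$b]], k)
  }
  vapply(seq_along(bonds), function(k) {
    from <- bonds[[k]]$a; to <- bonds[[k]]$b
    seen <- rep(FALSE, n)
    seen[from] <- TRUE
    queue <- from
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        if (e == k) next
        b <- bonds[[e]]
        w <- if (b$a == v) b$b else b$a
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1L))
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Atoms become nodes with a fixed-length feature vector (element one-hot
#' over B/C/N/O/F/P/S/Cl/Br/I plus "other", formal-charge bucket one-hot,
#' aromatic flag, hybridization one-hot, chirality tag one-hot, heavy-atom
#' degree one-hot 0-6).  Every chemical bond is stored as two directed
#' edges sharing one feature vector (bond-type one-hot single/double/
#' triple/aromatic, in-ring flag, conjugated flag).  Hydrogens are
#' implicit.  Hybridization and conjugation follow a declared rule set
#' (aromatic or multiply-bonded atoms are sp2/sp), not a toolkit's
#' perception.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `molecular_graph`: list with `n_atoms`,
#'   `atoms` (data frame of per-atom annotations), `atom_features`
#'   (n_atoms x 31 matrix), `edges` (data frame `src`,`dst`, both directed
#'   copies of each bond), `edge_features` (matrix, one row per directed
#'   edge), and `smiles`.
#' @examples
#' g <- parse_smiles("c1ccccc1")
#' g$n_atoms            # 6
#' nrow(g$edges)        # 12 directed edges
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  parsed <- parse_smiles_tokens(tokenize_smiles(smiles), smiles)
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  n <- length(atoms)

  degree <- integer(n)
  mult <- lapply(seq_len(n), function(i) character(0))  # incident bond codes
  for (b in bonds) {
    degree[b$a] <- degree[b$a] + 1L
    degree[b$b] <- degree[b$b] + 1L
    mult[[b$a]] <- c(mult[[b$a]], b$code)
    mult[[b$b]] <- c(mult[[b$b]], b$code)
  }

  hybrid <- vapply(seq_len(n), function(i) {
    if (!atoms[[i]]$element %in% c("B", "C", "N", "O", "P", "S")) return("other")
    codes <- mult[[i]]
    if (atoms[[i]]$aromatic || any(codes == "a")) return("sp2")
    if (any(codes == "t") || sum(codes == "d") >= 2L) return("sp")
    if (any(codes == "d")) return("sp2")
    "sp3"
  }, character(1L))

  in_ring <- ring_bond_flags(n, bonds)
  sp2ish <- hybrid %in% c("sp", "sp2")
  conj <- vapply(seq_along(bonds), function(k) {
    b <- bonds[[k]]
    b$code == "a" || (sp2ish[b$a] && sp2ish[b$b])
  }, logical(1L))

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, character(1L), "element"),
    aromatic = vapply(atoms, `[[`, logical(1L), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1L), "charge"),
    chirality = vapply(atoms, `[[`, integer(1L), "chirality"),
    degree = degree,
    hybridization = hybrid,
    stringsAsFactors = FALSE)

  atom_features <- t(vapply(seq_len(n), function(i) {
    a <- atom_df[i, ]
    elem <- numeric(length(ATOM_ELEMENTS) + 1L)
    j <- match(a$element, ATOM_ELEMENTS)
    elem[if (is.na(j)) length(elem) else j] <- 1
    chg <- numeric(5L)
    chg[min(max(a$charge, -2L), 2L) + 3L] <- 1
    hyb <- numeric(4L)
    hyb[match(a$hybridization, c("sp", "sp2", "sp3", "other"))] <- 1
    chir <- numeric(3L)
    chir[a$chirality + 1L] <- 1
    deg <- numeric(7L)
    deg[min(a$degree, 6L) + 1L] <- 1
    c(elem, chg, a$aromatic * 1, hyb, chir, deg)
  }, numeric(31L)))

  m <- length(bonds)
  src <- integer(2L * m); dst <- integer(2L * m)
  edge_features <- matrix(0, 2L * m, 6L)
  codes <- c(s = 1L, d = 2L, t = 3L, a = 4L)
  for (k in seq_along(bonds)) {
    b <- bonds[[k]]
    feat <- numeric(6L)
    feat[codes[[b$code]]] <- 1
    feat[5L] <- in_ring[k] * 1
    feat[6L] <- conj[k] * 1
    src[2L * k - 1L] <- b$a; dst[2L * k - 1L] <- b$b
    src[2L * k] <- b$b; dst[2L * k] <- b$a
    edge_features[2L * k - 1L, ] <- feat
    edge_features[2L * k, ] <- feat
  }

  structure(list(
    n_atoms = n,
    atoms = atom_df,
    atom_features = atom_features,
    edges = data.frame(src = src, dst = dst),
    edge_features = edge_features,
    smiles = smiles), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("Molecular graph of '%s': %d atoms, %d bonds (%d directed edges)\n",
              x$smiles, x$n_atoms, nrow(x$edges) / 2L, nrow(x$edges)))
  invisible(x)
}

#' Fit a token vocabulary from a corpus of token lists
#'
#' Ids are assigned by first appearance across the corpus; id 0 is reserved
#' for padding.  The map is order-sensitive: the same corpus in the same
#' order always yields the same map.
#'
#' @param corpus list of character vectors of tokens.
#' @return named integer vector mapping token to id (1-based for real
#'   tokens; padding id 0 is implicit), with attribute `unknown_id` = the
#'   id reserved for out-of-vocabulary tokens at prediction time.
#' @export
fit_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- unique(unlist(corpus, use.names = FALSE))
  ids <- seq_along(toks)
  names(ids) <- toks
  attr(ids, "unknown_id") <- length(toks) + 1L
  ids
}

# Map tokens to ids; out-of-vocabulary tokens get the unknown id.
tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- attr(vocab, "unknown_id")
  as.integer(ids)
}

#' Pad or cut a token id vector to a fixed length
#'
#' @param ids integer vector of token ids (0 = padding).
#' @param L_s target length, `>= 1`.
#' @return object of class `token_sequence`: list with `token_ids`
#'   (length `L_s`, zero-padded at the tail) and `valid_length`
#'   (`min(length(ids), L_s)`; excess tokens are dropped from the tail).
#' @export
pad_or_cut <- function(ids, L_s) {
  stopifnot(L_s >= 1L)
  ids <- as.integer(ids)
  k <- min(length(ids), L_s)
  out <- integer(L_s)
  if (k > 0L) out[seq_len(k)] <- ids[seq_len(k)]
  # id 0 only ever marks padding, so trailing zeros never count as valid;
  # this makes the operation idempotent
  nz <- which(out != 0L)
  valid <- if (length(nz) > 0L) max(nz) else 0L
  structure(list(token_ids = out, valid_length = valid),
            class = "token_sequence")
}
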