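# Reverse-mode automatic differentiation on a linear tape.
#
# Every differentiable value is a node: an environment holding a numeric
# matrix `value`, an accumulated gradient `grad` (filled during the backward
# sweep), and a `backfn` closure that pushes the node's gradient into its
# parents.  Nodes are appended to the tape in creation order, so a single
# reverse loop over the tape is a valid topological order.  All values are
# dense base-R matrices; batches are rows.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# Leaf node: a parameter or input wrapped onto the tape.
ad_leaf <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_node(tape, value)
}

# Constant: identical to a leaf; gradients may accumulate but are ignored.
ad_const <- ad_leaf

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backward sweep from `root` (must be 1x1).  After the call every node
# reachable from root holds d root / d node in `grad`.
ad_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node$grad)
  }
  invisible(NULL)
}

# ---- primitive operations ------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

# Add a 1 x d bias row to every row of an n x d matrix.
ad_addbias <- function(tape, a, b) {
  val <- sweep(a$value, 2L, as.vector(b$value), "+")
  ad_node(tape, val, function(g) {
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), 1L))
  })
}

# Multiply by a raw (non-node) scalar or conforming matrix/vector mask.
ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, function(g) ad_accum(a, g * k))
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, function(g) ad_accum(a, g * mask))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, function(g) ad_accum(a, g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  s <- tanh(a$value)
  ad_node(tape, s, function(g) ad_accum(a, g * (1 - s * s)))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), function(g) ad_accum(a, g / a$value))
}

# Clamp into [lo, hi]; gradient is passed through only on the interior.
ad_clamp <- function(tape, a, lo, hi) {
  inside <- a$value > lo & a$value < hi
  ad_node(tape, pmin(pmax(a$value, lo), hi), function(g) ad_accum(a, g * inside))
}

# Row gather: out[r, ] = a[idx[r], ].  Backward scatter-adds.
ad_gather <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], function(g) {
    gp <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(g, idx)
    gp[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, gp)
  })
}

# Segment sum: out[s, ] = sum of rows of a with group == s, s in 1..ngroups.
ad_segsum <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  out <- matrix(0, ngroups, ncol(a$value))
  agg <- rowsum(a$value, group)
  out[as.integer(rownames(agg)), ] <- agg
  ad_node(tape, out, function(g) ad_accum(a, g[group, , drop = FALSE]))
}

# Segment softmax over the rows of an n x 1 logit column, normalizing within
# each group.  Max-shifted for stability.
ad_segsoftmax <- function(tape, a, group) {
  x <- as.vector(a$value)
  group <- as.integer(group)
  m <- stats::ave(x, group, FUN = max)
  e <- exp(x - m)
  s <- stats::ave(e, group, FUN = sum)
  p <- e / s
  ad_node(tape, matrix(p, ncol = 1L), function(g) {
    g <- as.vector(g)
    dot <- stats::ave(p * g, group, FUN = sum)
    ad_accum(a, matrix(p * (g - dot), ncol = 1L))
  })
}

ad_cbind <- function(tape, ...) {
  parents <- list(...)
  widths <- vapply(parents, function(p) ncol(p$value), integer(1L))
  val <- do.call(cbind, lapply(parents, function(p) p$value))
  ad_node(tape, val, function(g) {
    at <- 0L
    for (k in seq_along(parents)) {
      ad_accum(parents[[k]], g[, at + seq_len(widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  })
}

ad_sum <- function(tape, a) {
  dims <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1L, 1L), function(g) {
    ad_accum(a, matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}

ad_mean <- function(tape, a) {
  ad_scale(tape, ad_sum(tape, a), 1 / length(a$value))
}

# Row-wise sums: n x d -> n x 1.
ad_rowsums <- function(tape, a) {
  d <- ncol(a$value)
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), function(g) {
    ad_accum(a, matrix(as.vector(g), nrow(a$value), d))
  })
}

# Scale each row of an n x d node by the matching entry of an n x 1 node.
ad_rowscale <- function(tape, a, s) {
  sv <- as.vector(s$value)
  ad_node(tape, a$value * sv, function(g) {
    ad_accum(a, g * sv)
    ad_accum(s, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

# 1 - x, elementwise.
ad_one_minus <- function(tape, a) {
  ad_node(tape, 1 - a$value, function(g) ad_accum(a, -g))
}

# Affine layer X W (+ b).
ad_linear <- function(tape, x, w, b = NULL) {
  out <- ad_mm(tape, x, w)
  if (!is.null(b)) out <- ad_addbias(tape, out, b)
  out
}

# Inverted dropout with a raw pre-drawn mask (already scaled by 1/(1-p)).
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  mask <- (stats::runif(length(a$value)) >= rate) / (1 - rate)
  ad_scale(tape, a, matrix(mask, nrow(a$value), ncol(a$value)))
}
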