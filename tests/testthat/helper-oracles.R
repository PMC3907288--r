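# Independent brute-force oracles. These never share code with the DP
# engine: scores come from exhaustive enumeration of internal-state
# assignments, reconstructions from filtering that enumeration.

# All internal-state assignments of a rooted or unrooted tree for one
# character, as a matrix (rows = assignments, cols = internal node ids in
# increasing order). States enumerated over the observed leaf range (any
# optimum can be clamped into it under the |i-j| cost).
.oracleGrid <- function(tree, x) {
  ntip <- length(tree$tip.label)
  internal <- sort(unique(as.vector(tree$edge[tree$edge > ntip])))
  rng <- seq(min(x), max(x))
  g <- as.matrix(expand.grid(rep(list(rng), length(internal))))
  colnames(g) <- internal
  g
}

# Total Wagner cost of every assignment; returns list(min, grid, costs).
bruteWagnerAll <- function(tree, x) {
  ntip <- length(tree$tip.label)
  stopifnot(setequal(names(x), tree$tip.label))
  g <- .oracleGrid(tree, x)
  stateOf <- function(node) {
    if (node <= ntip) rep(x[[tree$tip.label[node]]], nrow(g))
    else g[, as.character(node)]
  }
  costs <- rep(0, nrow(g))
  for (e in seq_len(nrow(tree$edge))) {
    costs <- costs + abs(stateOf(tree$edge[e, 1L]) - stateOf(tree$edge[e, 2L]))
  }
  list(min = min(costs), grid = g, costs = costs)
}

bruteWagner <- function(tree, x) bruteWagnerAll(tree, x)$min

# Minimal reconstruction under the parent-first tie policy, obtained by
# filtering the exhaustive optimum set: process nodes root-first; at each
# node keep assignments minimizing (primary tie key, state). For "closest"
# the key is |s - parent|, for "acctran" its negation.
oracleReconstruction <- function(tree, x, rootState = 0L,
                                 policy = c("closest", "acctran")) {
  policy <- match.arg(policy)
  stopifnot(ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  ba <- bruteWagnerAll(tree, x)
  keep <- which(ba$costs == ba$min)
  g <- ba$grid[keep, , drop = FALSE]
  root <- ntip + 1L
  # parent-first node order: root, then children along edges (preorder)
  E <- stats::reorder(tree, "postorder")$edge
  ord <- root
  for (e in rev(seq_len(nrow(E)))) if (E[e, 2L] > ntip) ord <- c(ord, E[e, 2L])
  parentOf <- function(v) if (v == root) NA_integer_ else E[E[, 2L] == v, 1L]
  chosen <- integer(0)
  for (v in ord) {
    p <- parentOf(v)
    pstate <- if (is.na(p)) rootState
      else if (p <= ntip) x[[tree$tip.label[p]]]
      else chosen[[as.character(p)]]
    s <- g[, as.character(v)]
    key <- if (policy == "closest") abs(s - pstate) else -abs(s - pstate)
    g <- g[key == min(key), , drop = FALSE]
    s <- g[, as.character(v)]
    g <- g[s == min(s), , drop = FALSE]
    chosen[[as.character(v)]] <- g[1L, as.character(v)]
  }
  full <- integer(ntip + tree$Nnode)
  full[seq_len(ntip)] <- x[tree$tip.label]
  full[as.integer(names(chosen))] <- chosen
  full
}

# Gain/loss tallies implied by a full node-state vector.
oracleTally <- function(tree, states) {
  E <- tree$edge
  d <- states[E[, 2L]] - states[E[, 1L]]
  c(gains = sum(d > 0L), losses = sum(d < 0L))
}

# Per-character minimal lengths over every unrooted topology (informative
# iff the minimum varies across topologies).
bruteInformative <- function(x) {
  tops <- phangorn::allTrees(length(x), rooted = FALSE,
                             tip.label = names(x))
  lens <- vapply(tops, bruteWagner, numeric(1), x = x)
  max(lens) > min(lens)
}
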