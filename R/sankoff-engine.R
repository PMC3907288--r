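# Ordered-multistate (Wagner) parsimony engine.
#
# Characters are ordered integers 0..k-1 with linear cost |i - j| between
# states, changes allowed in both directions. Dynamic programming follows
# Sankoff, specialised to the linear cost: the min-plus convolution of a
# cost vector with |.| is computed by a forward/backward running-minimum
# pass in O(k) instead of O(k^2). All per-node vectors are k x nchar
# matrices so every character is scored in one pass.

# Min-plus convolution with the linear (Wagner) cost: out[s] =
# min_t (|s - t| + M[t]). Idempotent, so subdividing a branch changes
# nothing.
.mc <- function(M) {
  k <- nrow(M)
  for (i in 2:k) M[i, ] <- pmin(M[i, ], M[i - 1L, ] + 1)
  for (i in (k - 1L):1L) M[i, ] <- pmin(M[i, ], M[i + 1L, ] + 1)
  M
}

# Leaf cost-to-go already convolved over the leaf's branch: |s - observed|.
.leafMC <- function(k, obs) abs(outer(0:(k - 1L), obs, "-"))

# Bottom-up (postorder) pass. S is a taxa x characters integer state
# matrix with row names; rows are looked up by tip label. Returns, for
# every node, the subtree cost vector A (internal nodes only) and its
# branch-convolved form MCA (all nodes), plus the postorder edge list.
.sankoffDown <- function(tree, S, k) {
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  nchar <- ncol(S)
  Sm <- S[po$tip.label, , drop = FALSE]
  A <- vector("list", nn)
  MCA <- vector("list", nn)
  for (i in seq_len(ntip)) MCA[[i]] <- .leafMC(k, Sm[i, ])
  zero <- matrix(0, k, nchar)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    if (ch > ntip) MCA[[ch]] <- .mc(A[[ch]])
    A[[p]] <- if (is.null(A[[p]])) zero + MCA[[ch]] else A[[p]] + MCA[[ch]]
  }
  root <- E[nrow(E), 1L]
  list(tree = po, edge = E, ntip = ntip, nnode = nn, root = root,
       nchar = nchar, k = k, A = A, MCA = MCA, states = Sm)
}

# Per-character minimal lengths and their sum for a scored tree.
.lengthFromDown <- function(down) {
  per_char <- .colMins(down$A[[down$root]])
  list(per_char = per_char, total = sum(per_char))
}

# Top-down (preorder) pass: U[[v]] is the cost of the whole tree minus the
# subtree below v, as a function of the state at the v-side attachment
# point of the branch above v (already convolved over that branch).
.sankoffUp <- function(down) {
  E <- down$edge
  U <- vector("list", down$nnode)
  U[[down$root]] <- matrix(0, down$k, down$nchar)
  for (e in rev(seq_len(nrow(E)))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    U[[ch]] <- .mc(U[[p]] + down$A[[p]] - down$MCA[[ch]])
  }
  U
}

# Total tree length after attaching a new terminal with branch-convolved
# cost matrix L (k x nchar) onto each branch, enumerated in postorder.
.attachScores <- function(down, up, L) {
  E <- down$edge
  out <- numeric(nrow(E))
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2L]
    out[e] <- sum(.colMins(down$MCA[[ch]] + up[[ch]] + L))
  }
  out
}

# Insert a new tip on the branch (u, v) of a topology-only phylo object.
# Tips keep ids 1..n, so existing ids > n shift by one.
.attachTip <- function(tree, u, v, label) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  E <- tree$edge
  E[E > n] <- E[E > n] + 1L
  if (u > n) u <- u + 1L
  if (v > n) v <- v + 1L
  w <- n + m + 2L
  row <- which(E[, 1L] == u & E[, 2L] == v)
  E[row, 2L] <- w
  E <- rbind(E, c(w, v), c(w, n + 1L))
  out <- list(edge = E, tip.label = c(tree$tip.label, label),
              Nnode = m + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out
}

# Stepwise (random-sequential) addition tree for a given taxon order,
# choosing at each step the attachment branch of minimal total length
# (first branch in postorder enumeration on ties).
.additionTree <- function(S, k, taxon_order) {
  first3 <- taxon_order[1:3]
  tree <- ape::read.tree(text = sprintf("(%s,%s,%s);",
                                        first3[1], first3[2], first3[3]))
  for (lab in taxon_order[-(1:3)]) {
    down <- .sankoffDown(tree, S, k)
    up <- .sankoffUp(down)
    L <- .leafMC(k, S[lab, ])
    sc <- .attachScores(down, up, L)
    e <- which.min(sc)
    tree <- .attachTip(down$tree, down$edge[e, 1L], down$edge[e, 2L], lab)
    tree <- stats::reorder(tree, "cladewise")
  }
  tree
}

# Uniform random unrooted labelled topology by random sequential addition
# to a uniformly chosen branch (every topology has probability
# 1/(2n-5)!!).
.randomTopology <- function(labels) {
  labels <- sample(labels)
  tree <- ape::read.tree(text = sprintf("(%s,%s,%s);",
                                        labels[1], labels[2], labels[3]))
  for (lab in labels[-(1:3)]) {
    E <- tree$edge
    e <- sample.int(nrow(E), 1L)
    tree <- .attachTip(tree, E[e, 1L], E[e, 2L], lab)
  }
  stats::reorder(tree, "cladewise")
}

# Best-neighbour NNI hill climbing; strictly improving sweeps, first
# minimal neighbour on ties.
.nniRefine <- function(tree, S, k, max_sweeps = 5L) {
  len <- .lengthFromDown(.sankoffDown(tree, S, k))$total
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    nbs <- phangorn::nni(tree)
    lens <- vapply(nbs, function(nb)
      .lengthFromDown(.sankoffDown(nb, S, k))$total, numeric(1))
    if (min(lens) >= len) break
    best <- which.min(lens)
    tree <- nbs[[best]]
    len <- lens[best]
  }
  list(tree = tree, length = len)
}
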