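.statesFor <- function(tree, m) {
  stopifnot(is(m, "CodedCensus"))
  .assertPhylo(tree)
  S <- codedStates(m)
  .assertLeafMatch(tree, rownames(S))
  S
}

#' Wagner parsimony length of a tree
#'
#' Scores a tree against an ordered multistate character matrix under
#' Wagner parsimony: the cost of changing between states i and j on a
#' branch is |i - j| and changes are allowed in both directions. Each
#' character's minimal cost is found by Sankoff dynamic programming with
#' linear-cost (running minimum) state vectors; the score is independent of
#' root placement.
#'
#' @param tree a \code{phylo} whose tip labels equal the matrix taxa
#'   (rooted or unrooted; polytomies allowed).
#' @param m a [CodedCensus-class].
#' @return A list with \code{total} (the tree length in steps) and
#'   \code{perCharacter} (named integer vector of per-character lengths).
#' @examples
#' m <- DomainCensus(matrix(c(1L, 3L, 6L, 2L, 2L, 2L), 3, 2,
#'        dimnames = list(c("a", "b", "c"), c("a.1.1.1", "b.1.1.1"))),
#'        c("A", "B", "E"))
#' wagnerLength(ape::read.tree(text = "((a,b),c);"), encodeOccurrence(m))
#' @export
wagnerLength <- function(tree, m) {
  S <- .statesFor(tree, m)
  down <- .sankoffDown(tree, S, stateCount(m))
  len <- .lengthFromDown(down)
  list(total = len$total,
       perCharacter = setNames(len$per_char, colnames(S)))
}

#' Parsimony-informative characters
#'
#' A character is parsimony informative when its minimal length varies
#' across tree topologies. For ordered characters the minimal length over
#' all binary topologies is the state range (taxa arranged along a
#' caterpillar in state order), and the maximal minimal length is attained
#' on the star tree; a character is therefore informative exactly when its
#' star-tree length exceeds its range. Both quantities are verified against
#' exhaustive topology enumeration in the package tests.
#'
#' @param m a [CodedCensus-class] with at least 4 taxa.
#' @return Character vector of informative character (column) names; the
#'   full logical mask is attached as attribute \code{"mask"}.
#' @export
parsimonyInformative <- function(m) {
  stopifnot(is(m, "CodedCensus"))
  S <- codedStates(m)
  if (nrow(S) < 4L)
    stop("informativeness needs at least 4 taxa", call. = FALSE)
  rng <- .charRange(S)
  star <- .charStarLength(S, stateCount(m))
  mask <- star > rng
  out <- colnames(S)[mask]
  attr(out, "mask") <- setNames(mask, colnames(S))
  out
}

.charRange <- function(S) {
  apply(S, 2L, max) - apply(S, 2L, min)
}

.charStarLength <- function(S, k) {
  tot <- matrix(Inf, k, ncol(S))
  for (s in 0:(k - 1L)) tot[s + 1L, ] <- colSums(abs(S - s))
  .colMins(tot)
}

#' Fit statistics of a scored tree
#'
#' Computes the tree length, ensemble retention index and, optionally, the
#' g1 skewness of the length distribution over random topologies. The
#' retention index is \eqn{RI = (G - S)/(G - M)} with sums taken over
#' parsimony-informative characters, where S is the observed number of
#' steps, M the minimal steps attainable on any topology (the ordered-state
#' range) and G the maximal steps (the star-tree length). g1 is the
#' standardized third moment of the lengths of \code{nRandomTrees}
#' topologies drawn uniformly at random (random sequential addition to a
#' uniformly chosen branch); strongly left-skewed (negative) values
#' indicate phylogenetic signal.
#'
#' @param tree a \code{phylo} over the matrix taxa.
#' @param m a [CodedCensus-class].
#' @param nRandomTrees number of random topologies for g1 (0 skips g1).
#' @param seed RNG seed for the random topologies (required when
#'   \code{nRandomTrees > 0}).
#' @return A list with \code{treeLength}, \code{ri}, \code{g1},
#'   \code{nInformative} and the per-character \code{steps}, \code{minSteps}
#'   and \code{maxSteps}.
#' @export
fitStatistics <- function(tree, m, nRandomTrees = 0L, seed = NULL) {
  S <- .statesFor(tree, m)
  k <- stateCount(m)
  obs <- wagnerLength(tree, m)$perCharacter
  rng <- .charRange(S)
  star <- .charStarLength(S, k)
  info <- star > rng
  ri <- if (any(info) && sum(star[info] - rng[info]) > 0) {
    (sum(star[info]) - sum(obs[info])) / sum(star[info] - rng[info])
  } else NA_real_
  g1 <- NA_real_
  if (nRandomTrees > 0L) {
    if (is.null(seed)) stop("g1 needs a seed", call. = FALSE)
    set.seed(seed)
    lens <- vapply(seq_len(nRandomTrees), function(i) {
      rt <- .randomTopology(rownames(S))
      .lengthFromDown(.sankoffDown(rt, S, k))$total
    }, numeric(1))
    g1 <- .momentSkewness(lens)
  }
  list(treeLength = sum(obs), ri = ri, g1 = g1, nInformative = sum(info),
       steps = obs, minSteps = setNames(rng, colnames(S)),
       maxSteps = setNames(star, colnames(S)))
}

# Moment skewness m3 / m2^(3/2) of a sample.
.momentSkewness <- function(x) {
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Search configuration for parsimony tree inference
#'
#' @param nStarts number of random-addition starting trees (a
#'   neighbour-joining style distance tree is always added as one more
#'   start when \code{njStart} is TRUE).
#' @param njStart include a distance (Manhattan on coded states)
#'   neighbour-joining starting tree.
#' @param maxSweeps maximal number of NNI improvement sweeps per start.
#' @param exhaustiveMax taxon count up to which the search enumerates all
#'   unrooted topologies instead of hill climbing (exact optimum).
#' @return A list of class \code{"searchConfig"}.
#' @export
searchConfig <- function(nStarts = 3L, njStart = TRUE, maxSweeps = 5L,
                         exhaustiveMax = 6L) {
  structure(list(nStarts = as.integer(nStarts), njStart = isTRUE(njStart),
                 maxSweeps = as.integer(maxSweeps),
                 exhaustiveMax = as.integer(exhaustiveMax)),
            class = "searchConfig")
}

#' Heuristic maximum-parsimony tree search
#'
#' Finds a minimum-length unrooted topology for an ordered multistate
#' matrix. For small taxon sets (\code{<= config$exhaustiveMax}) all
#' unrooted topologies are enumerated and the exact optimum returned. For
#' larger sets the search runs stepwise random-addition starts (plus an
#' optional neighbour-joining start) improved by strictly-improving NNI
#' sweeps; the best tree over all starts is returned. Deterministic for a
#' fixed seed.
#'
#' @param m a [CodedCensus-class] with at least 4 taxa.
#' @param config a [searchConfig()] list.
#' @param seed integer RNG seed for the random addition orders.
#' @return A list with \code{tree} (unrooted \code{phylo}), \code{length}
#'   (steps) and \code{stats} (the [fitStatistics()] of the tree, without
#'   g1).
#' @export
parsimonySearch <- function(m, config = searchConfig(), seed = 1L) {
  stopifnot(is(m, "CodedCensus"))
  S <- codedStates(m)
  k <- stateCount(m)
  if (nrow(S) < 4L) stop("tree search needs at least 4 taxa", call. = FALSE)
  if (nrow(S) <= config$exhaustiveMax) {
    cand <- phangorn::allTrees(nrow(S), rooted = FALSE,
                               tip.label = rownames(S))
    lens <- vapply(cand, function(tr)
      .lengthFromDown(.sankoffDown(tr, S, k))$total, numeric(1))
    best <- which.min(lens)
    tree <- cand[[best]]
    len <- lens[best]
  } else {
    set.seed(seed)
    starts <- list()
    if (config$njStart) {
      d <- stats::dist(S, method = "manhattan")
      nj <- ape::nj(d)
      nj$edge.length <- NULL
      starts <- c(starts, list(nj))
    }
    for (i in seq_len(config$nStarts)) {
      ord <- sample(rownames(S))
      starts <- c(starts, list(.additionTree(S, k, ord)))
    }
    res <- lapply(starts, .nniRefine, S = S, k = k,
                  max_sweeps = config$maxSweeps)
    lens <- vapply(res, `[[`, numeric(1), "length")
    best <- which.min(lens)
    tree <- res[[best]]$tree
    len <- lens[best]
  }
  list(tree = tree, length = len, stats = fitStatistics(tree, m))
}

#' Lundberg rooting with a hypothetical all-ancestral taxon
#'
#' Roots a most-parsimonious unrooted tree by attaching a hypothetical
#' ancestor that carries the declared ancestral state at every character
#' (state 0 for trees of life, the maximal state k-1 for trees of domains)
#' to the branch on which the attachment increases total tree length the
#' least. Ties are broken by the first branch in a deterministic postorder
#' enumeration. The returned tree is rooted on the selected branch; the
#' chosen branch, the length increase and whether the tie rule fired are
#' attached as attribute \code{"lundberg"}.
#'
#' @param tree an unrooted \code{phylo} over the matrix taxa.
#' @param m a [CodedCensus-class].
#' @param ancestorState the ancestral state of every character (a single
#'   integer in 0..k-1).
#' @return A rooted \code{phylo}.
#' @export
lundbergRoot <- function(tree, m, ancestorState = 0L) {
  S <- .statesFor(tree, m)
  k <- stateCount(m)
  if (ape::is.rooted(tree))
    stop("lundbergRoot expects an unrooted tree", call. = FALSE)
  ancestorState <- as.integer(ancestorState)
  if (ancestorState < 0L || ancestorState >= k)
    stop("ancestorState must lie in 0..(k-1)", call. = FALSE)
  down <- .sankoffDown(tree, S, k)
  up <- .sankoffUp(down)
  L <- matrix(abs(0:(k - 1L) - ancestorState), k, down$nchar)
  sc <- .attachScores(down, up, L)
  base <- .lengthFromDown(down)$total
  inc <- sc - base
  e <- which.min(inc)
  v <- down$edge[e, 2L]
  out_tips <- if (v <= down$ntip) down$tree$tip.label[v] else
    ape::extract.clade(down$tree, v)$tip.label
  rooted <- ape::root(down$tree, outgroup = out_tips, resolve.root = TRUE)
  attr(rooted, "lundberg") <- list(
    edge = down$edge[e, ], increase = inc[e],
    tie = sum(inc == inc[e]) > 1L, ancestorState = ancestorState)
  rooted
}

#' Minimal ancestral-state reconstruction
#'
#' Assigns one state per character to every node of a rooted tree such
#' that the implied number of Wagner steps is minimal. The assignment is
#' made parent-first (preorder): at the root the admissible minimal state
#' closest to the polarization ancestor state is chosen, and at every other
#' node the admissible state that keeps the subtree optimal given the
#' parent's state. Remaining ties are resolved by the named policy:
#' \code{"closest"} (default; the admissible state closest to the parent,
#' delaying change toward the tips, DELTRAN-like) or \code{"acctran"}
#' (the admissible state farthest from the parent, pulling change toward
#' the root). The total implied change equals [wagnerLength()] under every
#' policy.
#'
#' @param tree a rooted \code{phylo} (see [lundbergRoot()]).
#' @param m a [CodedCensus-class].
#' @param policy tie-resolution policy, \code{"closest"} or
#'   \code{"acctran"} (\code{"deltran"} is accepted as an alias of
#'   \code{"closest"}).
#' @param rootState polarization ancestor state used to resolve ties at the
#'   root (0 for trees of life, k-1 for trees of domains).
#' @return A list of class \code{"parsimonyReconstruction"} with the tree,
#'   the node x character state matrix (tips first, in the tree's internal
#'   numbering), the policy tag, the root state and the total implied
#'   length.
#' @export
ancestralStates <- function(tree, m, policy = c("closest", "deltran", "acctran"),
                            rootState = 0L) {
  policy <- match.arg(policy)
  if (policy == "deltran") policy <- "closest"
  S <- .statesFor(tree, m)
  k <- stateCount(m)
  if (!ape::is.rooted(tree))
    stop("ancestralStates needs a rooted tree; root it with lundbergRoot()",
         call. = FALSE)
  down <- .sankoffDown(tree, S, k)
  E <- down$edge
  nchar <- down$nchar
  nn <- down$nnode
  asg <- matrix(NA_integer_, nn, nchar)
  asg[seq_len(down$ntip), ] <- down$states
  sidx <- 0:(k - 1L)
  pick <- function(total, pstates) {
    tie <- abs(outer(sidx, pstates, "-"))
    if (policy == "acctran") tie <- (k - 1L) - tie
    total[!is.finite(total)] <- 1e7
    key <- total * 1e4 + tie * 100 + sidx
    max.col(-t(key), ties.method = "first") - 1L
  }
  root <- down$root
  asg[root, ] <- pick(down$A[[root]], rep(as.integer(rootState), nchar))
  for (e in rev(seq_len(nrow(E)))) {
    ch <- E[e, 2L]
    if (ch <= down$ntip) next
    p <- E[e, 1L]
    pst <- asg[p, ]
    total <- down$A[[ch]] + abs(outer(sidx, pst, "-"))
    asg[ch, ] <- pick(total, pst)
  }
  colnames(asg) <- colnames(S)
  len <- sum(abs(asg[E[, 1L], , drop = FALSE] - asg[E[, 2L], , drop = FALSE]))
  structure(list(tree = down$tree, states = asg, policy = policy,
                 rootState = as.integer(rootState), model = codingModel(m),
                 length = len, ntip = down$ntip),
            class = "parsimonyReconstruction")
}

#' @export
print.parsimonyReconstruction <- function(x, ...) {
  cat("Wagner parsimony reconstruction (", x$model, " model)\n", sep = "")
  cat("  ", x$ntip, " tips, ", ncol(x$states), " characters, length ",
      x$length, " steps, tie policy '", x$policy, "'\n", sep = "")
  invisible(x)
}

#' Bootstrap branch support
#'
#' Resamples characters with replacement, re-runs a reduced-effort search
#' per replicate (one random-addition start followed by one NNI sweep) and
#' reports, for every internal branch of the input tree, the percentage of
#' replicate trees containing the same bipartition.
#'
#' @param m a [CodedCensus-class].
#' @param tree the tree inferred from the same matrix.
#' @param nReplicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return A data.frame with one row per internal branch: the child node id
#'   in the input tree, the smaller-side tip set of the bipartition, and
#'   the support percentage in [0, 100].
#' @export
bootstrapSupport <- function(m, tree, nReplicates = 1000L, seed = 1L) {
  S <- .statesFor(tree, m)
  k <- stateCount(m)
  if (nReplicates < 1L) stop("nReplicates must be >= 1", call. = FALSE)
  set.seed(.deriveSeed(seed, "bootstrap"))
  ref <- .splitKeys(tree)
  counts <- setNames(numeric(length(ref$key)), ref$key)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(ncol(S), ncol(S), replace = TRUE)
    Sb <- S[, cols, drop = FALSE]
    colnames(Sb) <- paste0("c", seq_len(ncol(Sb)))
    bt <- .additionTree(Sb, k, sample(rownames(Sb)))
    bt <- .nniRefine(bt, Sb, k, max_sweeps = 1L)$tree
    hit <- .splitKeys(bt)$key
    counts[names(counts) %in% hit] <- counts[names(counts) %in% hit] + 1
  }
  data.frame(node = ref$node, tips = ref$tips,
             support = 100 * unname(counts) / nReplicates,
             stringsAsFactors = FALSE)
}

# Canonical bipartition keys of the internal branches of a tree: each
# internal edge is represented by the sorted tip-label set on the side not
# containing the alphabetically first label.
.splitKeys <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  E <- tree$edge
  inner <- E[E[, 2L] > ntip, 2L]
  root <- E[nrow(E), 1L]
  inner <- inner[inner != root]
  keys <- character(0); nodes <- integer(0); tipsets <- character(0)
  for (v in inner) {
    below <- ape::extract.clade(tree, v)$tip.label
    if (length(below) <= 1L || length(below) >= ntip - 1L) next
    side <- if (anchor %in% below) setdiff(tree$tip.label, below) else below
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, v)
    tipsets <- c(tipsets, paste(sort(below), collapse = ","))
  }
  list(key = keys, node = nodes, tips = tipsets)
}

#' Prune a tree to a taxon subset
#'
#' Returns the induced subtree on \code{keep}: branches to dropped taxa are
#' removed and resulting degree-2 nodes suppressed. The root is retained
#' whenever at least two of its descendant lineages survive; otherwise it
#' is suppressed with the chain of single-child nodes above the surviving
#' clade.
#'
#' @param tree a \code{phylo}.
#' @param keep character vector of tip labels to keep (at least 2, all
#'   present in the tree).
#' @return The induced \code{phylo}.
#' @export
pruneToTaxa <- function(tree, keep) {
  .assertPhylo(tree)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa in keep: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(keep) < 2L) stop("keep at least 2 taxa", call. = FALSE)
  ape::keep.tip(tree, keep)
}
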