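#' Nodal RMSD between two trees
#'
#' For every unordered pair of leaves the nodal distance is the number of
#' branches on the path connecting them (rooted trees are compared as
#' rooted, so paths may cross the root). The nodal RMSD of two trees on
#' the same leaf set is
#' \deqn{RMSD = \sqrt{\sum_{i<j} (d_1(i,j) - d_2(i,j))^2 / n_{pairs}}}
#' It is 0 exactly when the two leaf-pair distance matrices agree, and
#' grows with topological incongruence.
#'
#' @param t1,t2 \code{phylo} objects with identical leaf sets.
#' @return The RMSD (single non-negative number).
#' @export
nodalRMSD <- function(t1, t2) {
  .assertPhylo(t1); .assertPhylo(t2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ; only in first: {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ", "),
         "}; only in second: {",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ", "), "}",
         call. = FALSE)
  }
  d1 <- .nodalDistances(t1)
  d2 <- .nodalDistances(t2)[rownames(d1), rownames(d1)]
  up <- upper.tri(d1)
  sqrt(sum((d1[up] - d2[up])^2) / sum(up))
}

# Leaf-pair path lengths in branch counts.
.nodalDistances <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  stats::cophenetic(tr)
}

#' Guided randomization test of tree congruence
#'
#' Compares the observed nodal RMSD of two trees with its distribution
#' when the taxon positions are randomized while both topologies are kept
#' fixed: per replicate the leaf labels of the second tree are permuted
#' uniformly and the RMSD recomputed. The observed congruence is deemed
#' better than chance when the observed RMSD falls below the mean of the
#' random distribution. The empirical p-value uses add-one smoothing,
#' \eqn{p = (1 + \#\{RMSD_{rand} \le RMSD_{obs}\}) / (reps + 1)}, so a
#' perfect comparison reports 1/(reps+1) rather than 0.
#'
#' @param t1,t2 \code{phylo} objects with identical leaf sets.
#' @param reps number of randomization replicates.
#' @param seed RNG seed.
#' @return A list of class \code{"treeComparison"}: \code{rmsd},
#'   \code{randomMean}, \code{randomSd}, \code{nReplicates},
#'   \code{empiricalP}, \code{betterThanChance} and the replicate RMSD
#'   values.
#' @export
guidedRandomizationTest <- function(t1, t2, reps = 100L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  obs <- nodalRMSD(t1, t2)
  set.seed(.deriveSeed(seed, "compare"))
  rand <- vapply(seq_len(reps), function(r) {
    tp <- t2
    tp$tip.label <- sample(tp$tip.label)
    nodalRMSD(t1, tp)
  }, numeric(1))
  structure(list(rmsd = obs, randomMean = mean(rand), randomSd = sd(rand),
                 nReplicates = reps,
                 empiricalP = (1 + sum(rand <= obs)) / (reps + 1),
                 betterThanChance = obs < mean(rand), replicates = rand),
            class = "treeComparison")
}

#' @export
print.treeComparison <- function(x, ...) {
  cat("Nodal RMSD ", format(round(x$rmsd, 3), nsmall = 3),
      " vs random mean ", format(round(x$randomMean, 3), nsmall = 3),
      " (sd ", format(round(x$randomSd, 3), nsmall = 3), ", ",
      x$nReplicates, " replicates)\n", sep = "")
  cat("  empirical p = ", format(round(x$empiricalP, 4)), "; ",
      if (x$betterThanChance) "more congruent than chance expectation"
      else "not better than chance", "\n", sep = "")
  invisible(x)
}
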