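# Birth-duplication-loss simulator: fold-family repertoires evolving along
# a known taxon tree, with every event recorded so inference can be
# validated against ground truth.

#' Simulation configuration
#'
#' Parameters of the domain-repertoire simulator. Each fold family
#' originates exactly once, either in the root ancestor (depth 0; an
#' ancestral family of the progenote repertoire, present in all three
#' superkingdom stems) or on a branch, drawn with probability proportional
#' to exp(-originationBias * depth); bias > 0 tilts originations rootward
#' so that a sizeable universal (ABE) family core emerges alongside
#' recent superkingdom-specific families, as in real fold-family censuses.
#' After origination the family's abundance evolves along every descendant
#' branch by Poisson numbers of duplications (+1 each) and losses (-1
#' each, floored at 0; a lineage hitting 0 is extinct there and stays so).
#' Branch lengths are unitless, so all rates are per branch per family.
#'
#' @param nPerSuperkingdom named integer vector: taxa per superkingdom
#'   (each >= 4). The defaults give 50 taxa in total.
#' @param nFamilies number of fold families to originate.
#' @param duplicationRate Poisson mean of duplications per branch.
#' @param lossRate Poisson mean of losses per branch.
#' @param originationBias depth tilt of origination placement over
#'   {root, branches}: weight exp(-bias * depth); 0 = uniform, > 0
#'   rootward (more ancient/universal families).
#' @param skMultipliers named multipliers applied to duplication and loss
#'   rates on branches lying entirely inside one superkingdom clade.
#' @param seed mandatory RNG seed.
#' @return A list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nPerSuperkingdom = c(A = 16L, B = 17L, E = 17L),
                             nFamilies = 200L,
                             duplicationRate = 1.0,
                             lossRate = 0.2,
                             originationBias = 0.8,
                             skMultipliers = c(A = 1, B = 1, E = 1),
                             seed = 1L) {
  stopifnot(all(.SUPERKINGDOMS %in% names(nPerSuperkingdom)),
            duplicationRate >= 0, lossRate >= 0,
            all(skMultipliers >= 0), length(seed) == 1L)
  if (any(nPerSuperkingdom < 4L))
    stop("need at least 4 taxa per superkingdom", call. = FALSE)
  structure(list(nPerSuperkingdom = nPerSuperkingdom[.SUPERKINGDOMS],
                 nFamilies = as.integer(nFamilies),
                 duplicationRate = duplicationRate, lossRate = lossRate,
                 originationBias = originationBias,
                 skMultipliers = skMultipliers[.SUPERKINGDOMS],
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

#' Simulate a taxon tree with three superkingdom clades
#'
#' Draws a random rooted binary tree whose leaves fall into three labelled
#' monophyletic clades (Archaea, Bacteria, Eukarya), with Archaea basal:
#' ((Bacteria, Eukarya), Archaea). Leaf labels are the superkingdom letter
#' followed by an index (e.g. "A03"). Deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @return A rooted \code{phylo} without branch lengths.
#' @export
simulateTaxonTree <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(.deriveSeed(config$seed, "simulate"))
  clade <- function(s) {
    n <- config$nPerSuperkingdom[[s]]
    tr <- ape::rtree(n, br = NULL,
                     tip.label = sprintf("%s%02d", s, seq_len(n)))
    ape::write.tree(tr)
  }
  nwk <- sprintf("((%s,%s),%s);",
                 sub(";$", "", clade("B")), sub(";$", "", clade("E")),
                 sub(";$", "", clade("A")))
  ape::read.tree(text = nwk)
}

#' Simulate fold-family histories along a tree
#'
#' Runs the origination/duplication/loss process of a
#' [simulationConfig()] along a rooted taxon tree and returns both the
#' resulting abundance census and the complete ground truth (origination
#' branch and depth per family, and the per-branch abundance change of
#' every family). Families extinct in every sampled taxon are excluded
#' from the census but retained in the truth tables with
#' \code{survived = FALSE}.
#'
#' @param tree a rooted \code{phylo} with A/B/E-prefixed tip labels (see
#'   [simulateTaxonTree()]).
#' @param config a [simulationConfig()].
#' @return A list of class \code{"domainSimulation"}: \code{census} (a
#'   [DomainCensus-class]), \code{truth} (list with \code{families} and
#'   \code{events} data.frames), \code{tree} and \code{config}.
#' @export
simulateDomainHistories <- function(tree, config = simulationConfig()) {
  .assertPhylo(tree)
  stopifnot(inherits(config, "simulationConfig"))
  if (!ape::is.rooted(tree))
    stop("simulation needs a rooted tree", call. = FALSE)
  set.seed(.deriveSeed(config$seed, "simulate") + 7L)
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  nn <- ntip + po$Nnode
  # node depths in edges from the root
  depth <- integer(nn)
  for (e in rev(seq_len(nrow(E)))) depth[E[e, 2L]] <- depth[E[e, 1L]] + 1L
  # superkingdom of the clade below each node ("mixed" when heterogeneous)
  clade_sk <- character(nn)
  clade_sk[seq_len(ntip)] <- substr(po$tip.label, 1L, 1L)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    clade_sk[p] <- if (clade_sk[p] == "") clade_sk[ch]
      else if (clade_sk[p] == clade_sk[ch]) clade_sk[p] else "mixed"
  }
  mult <- rep(1, nrow(E))
  inside <- clade_sk[E[, 2L]] %in% .SUPERKINGDOMS
  mult[inside] <- config$skMultipliers[clade_sk[E[inside, 2L]]]
  # origination point: the root (depth 0) or the child node of a branch,
  # weighted by exp(-bias * depth)
  root <- E[nrow(E), 1L]
  cand <- c(root, E[, 2L])            # index 1 = root origination
  w <- exp(-config$originationBias * depth[cand])
  w <- w / sum(w)
  css <- sprintf("a.%d.1.1", seq_len(config$nFamilies))
  n_ff <- config$nFamilies
  orig_pick <- sample.int(length(cand), n_ff, replace = TRUE, prob = w)
  orig_edge <- orig_pick - 1L         # 0 = root, otherwise edge row
  preorder <- rev(seq_len(nrow(E)))
  abundance <- matrix(0L, nn, n_ff)
  abundance[root, orig_edge == 0L] <- 1L
  ev_list <- vector("list", nrow(E))
  for (ei in preorder) {
    p <- E[ei, 1L]; ch <- E[ei, 2L]
    a <- abundance[p, ]
    new_here <- orig_edge == ei
    a[new_here] <- 1L
    active <- a > 0L & !new_here
    nw <- a
    if (any(active)) {
      nd_ <- rpois(sum(active), config$duplicationRate * mult[ei])
      nl_ <- rpois(sum(active), config$lossRate * mult[ei])
      nw[active] <- pmax(0L, a[active] + nd_ - nl_)
    }
    abundance[ch, ] <- nw
    delta <- nw - abundance[p, ]
    chg <- which(delta != 0L)
    if (length(chg)) {
      ev_list[[ei]] <- data.frame(
        css = css[chg], parent = p, child = ch,
        delta = delta[chg],
        type = ifelse(new_here[chg], "origination",
                      ifelse(delta[chg] > 0L, "duplication", "loss")),
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  rownames(events) <- NULL
  cnt <- abundance[seq_len(ntip), , drop = FALSE]
  dimnames(cnt) <- list(po$tip.label, css)
  survived <- colSums(cnt) > 0L
  if (!any(survived))
    stop("simulation produced an all-zero census; increase rates or ",
         "lower the loss rate", call. = FALSE)
  gains <- tapply(events$delta > 0L, factor(events$css, levels = css), sum,
                  default = 0L)
  losses <- tapply(events$delta < 0L, factor(events$css, levels = css), sum,
                   default = 0L)
  orig_child <- ifelse(orig_edge == 0L, root, E[pmax(orig_edge, 1L), 2L])
  orig_parent <- ifelse(orig_edge == 0L, NA_integer_,
                        E[pmax(orig_edge, 1L), 1L])
  fam <- data.frame(
    css = css,
    originationParent = orig_parent,
    originationChild = orig_child,
    originationDepth = depth[orig_child],
    relDepth = depth[orig_child] / max(depth),
    trueGains = as.integer(gains), trueLosses = as.integer(losses),
    trueNet = as.integer(gains) - as.integer(losses),
    survived = unname(survived),
    stringsAsFactors = FALSE)
  census <- DomainCensus(cnt[, survived, drop = FALSE],
                         substr(po$tip.label, 1L, 1L))
  structure(list(census = census,
                 truth = list(families = fam, events = events),
                 tree = po, config = config),
            class = "domainSimulation")
}

#' Replay recorded simulation events
#'
#' Reconstructs the abundance matrix purely from the truth event table by
#' accumulating per-branch deltas from the root down. Bit-exact agreement
#' with the emitted census is an invariant of the simulator.
#'
#' @param sim a \code{domainSimulation}.
#' @return Integer matrix taxa x families (all simulated families,
#'   including extinct ones).
#' @export
replaySimulation <- function(sim) {
  stopifnot(inherits(sim, "domainSimulation"))
  tree <- sim$tree
  ev <- sim$truth$events
  css <- sim$truth$families$css
  ntip <- length(tree$tip.label)
  E <- stats::reorder(tree, "postorder")$edge
  nn <- ntip + tree$Nnode
  ab <- matrix(0L, nn, length(css), dimnames = list(NULL, css))
  root <- E[nrow(E), 1L]
  fam <- sim$truth$families
  ab[root, fam$css[is.na(fam$originationParent)]] <- 1L
  key <- paste(ev$parent, ev$child)
  for (e in rev(seq_len(nrow(E)))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    ab[ch, ] <- ab[p, ]
    hit <- key == paste(p, ch)
    if (any(hit)) ab[ch, ev$css[hit]] <- ab[ch, ev$css[hit]] + ev$delta[hit]
  }
  out <- ab[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the assignment table (readable by [readAssignmentTable()]), the
#' true tree in Newick, the truth tables and a JSON manifest recording the
#' configuration and seed, so a run can be reproduced byte for byte.
#'
#' @param sim a \code{domainSimulation}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
emitDataset <- function(sim, dir) {
  stopifnot(inherits(sim, "domainSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- censusCounts(sim$census)
  sk <- as.character(superkingdoms(sim$census))
  idx <- which(cnt > 0L, arr.ind = TRUE)
  tab <- data.frame(proteome_id = rownames(cnt)[idx[, 1L]],
                    superkingdom = sk[idx[, 1L]],
                    css = colnames(cnt)[idx[, 2L]],
                    count = cnt[idx],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$proteome_id, tab$css), , drop = FALSE]
  files <- c(assignments = file.path(dir, "assignments.tsv"),
             tree = file.path(dir, "tree.nwk"),
             families = file.path(dir, "truth_families.tsv"),
             events = file.path(dir, "truth_events.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write.table(tab, files["assignments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(sim$tree, files["tree"])
  write.table(sim$truth$families, files["families"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$events, files["events"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$nPerSuperkingdom <- as.list(cfg$nPerSuperkingdom)
  cfg$skMultipliers <- as.list(cfg$skMultipliers)
  jsonlite::write_json(cfg, files["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
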