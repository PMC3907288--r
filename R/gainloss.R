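#' Trace per-branch character-state changes
#'
#' Walks every branch of a reconstruction and emits one event per
#' (character, branch) on which the child state differs from the parent
#' state: a gain when the state increased, a loss when it decreased, with
#' magnitude |change|. The polarization edge leading into the root (from
#' the hypothetical ancestor) is excluded by default.
#'
#' @param rec a \code{parsimonyReconstruction} from [ancestralStates()].
#' @param includeRootEdge also emit events for the root's incoming
#'   polarization edge (ancestor state to root state).
#' @return A data.frame of events with columns \code{css}, \code{parent},
#'   \code{child}, \code{from}, \code{to}, \code{direction} (gain/loss) and
#'   \code{magnitude}; the character universe and the coding model are
#'   attached as attributes \code{"chars"} and \code{"model"}.
#' @export
traceChanges <- function(rec, includeRootEdge = FALSE) {
  stopifnot(inherits(rec, "parsimonyReconstruction"))
  E <- rec$tree$edge
  st <- rec$states
  chars <- colnames(st)
  from <- st[E[, 1L], , drop = FALSE]
  to <- st[E[, 2L], , drop = FALSE]
  d <- to - from
  idx <- which(d != 0L, arr.ind = TRUE)
  ev <- data.frame(
    css = chars[idx[, 2L]],
    parent = E[idx[, 1L], 1L],
    child = E[idx[, 1L], 2L],
    from = from[idx],
    to = to[idx],
    stringsAsFactors = FALSE)
  if (includeRootEdge) {
    ntip <- length(rec$tree$tip.label)
    root <- ntip + 1L
    rs <- st[root, ]
    ri <- which(rs != rec$rootState)
    if (length(ri)) {
      ev <- rbind(ev, data.frame(
        css = chars[ri], parent = NA_integer_, child = root,
        from = rec$rootState, to = unname(rs[ri]),
        stringsAsFactors = FALSE))
    }
  }
  ev$direction <- ifelse(ev$to > ev$from, "gain", "loss")
  ev$magnitude <- abs(ev$to - ev$from)
  ev <- ev[order(ev$css, ev$parent, ev$child), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "chars") <- chars
  attr(ev, "model") <- rec$model
  attr(ev, "policy") <- rec$policy
  ev
}

#' Tally gains and losses per fold family
#'
#' Aggregates traced events into per-family counts of the number of
#' branches on which the family was gained and lost (branch counting, not
#' magnitude weighted, unless \code{magnitudeWeighted}). The net is
#' gains - losses; a family is classified \code{gained} when net > 0,
#' \code{lost} when net < 0 and \code{unchanged} when net = 0.
#'
#' @param events event table from [traceChanges()].
#' @param chars character universe (families with zero events appear as
#'   unchanged); defaults to the universe recorded on \code{events}.
#' @param magnitudeWeighted count state-step magnitudes instead of
#'   branches.
#' @return A data.frame with one row per family: \code{css}, \code{gains},
#'   \code{losses}, \code{net}, \code{class}, \code{model}.
#' @export
tallyGainLoss <- function(events, chars = attr(events, "chars"),
                          magnitudeWeighted = FALSE) {
  if (is.null(chars)) chars <- sort(unique(events$css))
  w <- if (magnitudeWeighted) events$magnitude else rep(1L, nrow(events))
  g <- tapply(w[events$direction == "gain"],
              factor(events$css[events$direction == "gain"], levels = chars),
              sum, default = 0L)
  l <- tapply(w[events$direction == "loss"],
              factor(events$css[events$direction == "loss"], levels = chars),
              sum, default = 0L)
  net <- as.integer(g) - as.integer(l)
  rec <- data.frame(
    css = chars, gains = as.integer(g), losses = as.integer(l), net = net,
    class = ifelse(net > 0L, "gained", ifelse(net < 0L, "lost", "unchanged")),
    model = if (!is.null(attr(events, "model"))) attr(events, "model") else NA_character_,
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  rec
}

#' Epoch boundaries of the domain timeline
#'
#' The evolutionary timeline is partitioned into three epochs of relative
#' age nd: \emph{early} (0 <= nd < earlyEnd), \emph{intermediate}
#' (earlyEnd <= nd < lateStart) and \emph{late} (lateStart <= nd <= 1).
#' Defaults are 0.15 and 0.55, the ages at which the first complete
#' archaeal loss and the joint rise of superkingdom-specific archaeal and
#' eukaryal families are observed.
#'
#' @param earlyEnd exclusive upper bound of the early epoch.
#' @param lateStart inclusive lower bound of the late epoch.
#' @return A list of class \code{"epochBoundaries"}.
#' @export
epochBoundaries <- function(earlyEnd = 0.15, lateStart = 0.55) {
  if (!(0 < earlyEnd && earlyEnd < lateStart && lateStart <= 1))
    stop("need 0 < earlyEnd < lateStart <= 1", call. = FALSE)
  structure(list(earlyEnd = earlyEnd, lateStart = lateStart),
            class = "epochBoundaries")
}

#' Gain-to-loss ratio summary
#'
#' Sums gains and losses over all families and reports the gain-to-loss
#' ratio; when a relative-age map is supplied, all of a family's events are
#' binned into the epoch of the family's nd age and per-epoch totals and
#' ratios are added. Merged-epoch ratios are ratios of summed counts, never
#' means of ratios.
#'
#' @param records per-family tally from [tallyGainLoss()].
#' @param ndMap optional named numeric vector mapping css to relative age
#'   nd (required for epoch binning; must cover every family).
#' @param epochs an [epochBoundaries()] list.
#' @return A list of class \code{"gainLossSummary"} with
#'   \code{totalGains}, \code{totalLosses}, \code{ratio} (NA with
#'   \code{infinite = TRUE} when no losses), and, with \code{ndMap}, a
#'   \code{perEpoch} data.frame.
#' @export
ratioSummary <- function(records, ndMap = NULL, epochs = epochBoundaries()) {
  tg <- sum(records$gains)
  tl <- sum(records$losses)
  out <- list(totalGains = tg, totalLosses = tl,
              ratio = if (tl > 0) tg / tl else NA_real_,
              infinite = tl == 0 && tg > 0)
  if (!is.null(ndMap)) {
    miss <- setdiff(records$css, names(ndMap))
    if (length(miss))
      stop("nd missing for famil", if (length(miss) == 1L) "y: " else "ies: ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    ep <- assignEpoch(unname(ndMap[records$css]), epochs)
    g <- tapply(records$gains, ep, sum, default = 0L)
    l <- tapply(records$losses, ep, sum, default = 0L)
    out$perEpoch <- data.frame(
      epoch = levels(ep), gains = as.integer(g), losses = as.integer(l),
      ratio = ifelse(l > 0, as.numeric(g) / as.numeric(l), NA_real_),
      stringsAsFactors = FALSE)
  }
  class(out) <- "gainLossSummary"
  out
}

#' @export
print.gainLossSummary <- function(x, ...) {
  cat("Gain/loss summary: ", x$totalGains, " gains vs ", x$totalLosses,
      " losses", sep = "")
  if (x$infinite) cat(" (no losses: ratio infinite)\n")
  else cat(", gain-to-loss ratio ", format(round(x$ratio, 2), nsmall = 2),
           "\n", sep = "")
  if (!is.null(x$perEpoch)) {
    cat("  per epoch:\n")
    print(x$perEpoch, row.names = FALSE)
  }
  invisible(x)
}

#' Gain/loss analysis restricted to one superkingdom
#'
#' Prunes the tree of life to the proteomes of one superkingdom, drops
#' fold-family characters absent (state 0) from all kept taxa, recomputes
#' the ancestral reconstruction on the pruned tree and tallies gains and
#' losses. By default the pruned tree is the induced subtree of the global
#' topology (\code{mode = "reuse_topology"}); \code{mode = "re_search"}
#' instead re-runs the parsimony search on the reduced matrix and roots it
#' by the Lundberg method.
#'
#' @param m a [CodedCensus-class] in tree-of-life orientation.
#' @param tree the rooted global tree of life over all taxa of \code{m}.
#' @param sk superkingdom, one of \code{"A"}, \code{"B"}, \code{"E"}.
#' @param mode \code{"reuse_topology"} or \code{"re_search"}.
#' @param policy tie policy passed to [ancestralStates()].
#' @param config search configuration for \code{"re_search"}.
#' @param seed seed for \code{"re_search"}.
#' @param ndMap,epochs optional epoch binning, see [ratioSummary()].
#' @return A list with \code{records}, \code{summary}, \code{tree} (the
#'   pruned rooted tree) and \code{taxa}.
#' @export
superkingdomAnalysis <- function(m, tree, sk = c("A", "B", "E"),
                                 mode = c("reuse_topology", "re_search"),
                                 policy = "closest",
                                 config = searchConfig(), seed = 1L,
                                 ndMap = NULL, epochs = epochBoundaries()) {
  stopifnot(is(m, "CodedCensus"), m@taxaAre == "proteomes")
  sk <- match.arg(sk)
  mode <- match.arg(mode)
  taxa <- names(superkingdoms(m))[superkingdoms(m) == sk]
  if (length(taxa) < 4L)
    stop("superkingdom ", sk, " has fewer than 4 taxa", call. = FALSE)
  S <- codedStates(m)[taxa, , drop = FALSE]
  keep_ff <- colSums(S > 0L) > 0L
  sub <- .newCodedCensus(S[, keep_ff, drop = FALSE], m@k, m@symbols,
                         m@model, "proteomes",
                         superkingdoms(m)[taxa])
  if (mode == "reuse_topology") {
    st <- pruneToTaxa(tree, taxa)
    if (!ape::is.rooted(st)) st <- lundbergRoot(st, sub, 0L)
  } else {
    st <- lundbergRoot(parsimonySearch(sub, config, seed)$tree, sub, 0L)
  }
  rec <- ancestralStates(st, sub, policy = policy, rootState = 0L)
  ev <- traceChanges(rec)
  records <- tallyGainLoss(ev)
  list(records = records,
       summary = ratioSummary(records, ndMap = ndMap, epochs = epochs),
       tree = st, taxa = taxa)
}

#' Equal-sampling experiment
#'
#' Draws replicate subsamples of the same number of proteomes from each
#' superkingdom, rebuilds a tree per replicate, reconstructs ancestral
#' states and reports the per-superkingdom gain-to-loss ratio
#' distributions. This controls for the unequal numbers of sampled
#' proteomes per superkingdom.
#'
#' @param m a [CodedCensus-class] in tree-of-life orientation.
#' @param k proteomes sampled per superkingdom (without replacement).
#' @param reps number of replicates.
#' @param seed RNG seed (the whole experiment is deterministic given it).
#' @param config search effort per replicate (defaults to a reduced
#'   single-start search).
#' @param policy tie policy for the reconstructions.
#' @return A list with \code{ratios} (data.frame replicate x superkingdom)
#'   and \code{medians} (named vector of per-superkingdom median ratios).
#' @export
equalSamplingExperiment <- function(m, k = 34L, reps = 100L, seed = 1L,
                                    config = searchConfig(nStarts = 1L,
                                                          maxSweeps = 2L),
                                    policy = "closest") {
  stopifnot(is(m, "CodedCensus"), m@taxaAre == "proteomes")
  sk <- superkingdoms(m)
  for (s in .SUPERKINGDOMS) {
    if (sum(sk == s) < k)
      stop("superkingdom ", s, " has fewer than k = ", k, " taxa",
           call. = FALSE)
  }
  set.seed(.deriveSeed(seed, "sampling"))
  res <- matrix(NA_real_, reps, 3L, dimnames = list(NULL, .SUPERKINGDOMS))
  for (r in seq_len(reps)) {
    taxa <- unlist(lapply(.SUPERKINGDOMS, function(s)
      sample(names(sk)[sk == s], k)))
    S <- codedStates(m)[taxa, , drop = FALSE]
    keep_ff <- colSums(S > 0L) > 0L
    sub <- .newCodedCensus(S[, keep_ff, drop = FALSE], m@k, m@symbols,
                           m@model, "proteomes", sk[taxa])
    tr <- lundbergRoot(parsimonySearch(sub, config,
                                       seed = sample.int(2^30, 1L))$tree,
                       sub, 0L)
    for (s in .SUPERKINGDOMS) {
      ana <- superkingdomAnalysis(sub, tr, s, policy = policy)
      res[r, s] <- ana$summary$ratio
    }
  }
  list(ratios = as.data.frame(res),
       medians = apply(res, 2L, median, na.rm = TRUE),
       k = k, reps = reps, seed = seed)
}

#' Consensus gained/lost sets across coding models
#'
#' Keeps only the fold families classified the same way by the abundance
#' and occurrence reconstructions: gained in both, or lost in both.
#' Families on which the two models disagree (or that are unchanged in
#' either) are excluded.
#'
#' @param abundanceRecords,occurrenceRecords per-family tallies from
#'   [tallyGainLoss()] over a shared family universe.
#' @return A list with character vectors \code{gainedBoth} and
#'   \code{lostBoth}.
#' @export
consensusSets <- function(abundanceRecords, occurrenceRecords) {
  g <- function(rec, cls) rec$css[rec$class == cls]
  list(gainedBoth = sort(intersect(g(abundanceRecords, "gained"),
                                   g(occurrenceRecords, "gained"))),
       lostBoth = sort(intersect(g(abundanceRecords, "lost"),
                                 g(occurrenceRecords, "lost"))))
}
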