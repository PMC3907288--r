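#' Build a tree of domains (ToD)
#'
#' Reconstructs a parsimony tree in which the fold families are the taxa
#' and the proteomes the characters, then roots it by the Lundberg method
#' with an ancestor carrying the maximal state at every character (23 under
#' abundance coding, 1 under occurrence). This polarization treats high,
#' widespread abundance as ancestral: old families have had time to
#' accumulate duplicates across lineages, recent families are rare and
#' lineage specific.
#'
#' @param mt a [CodedCensus-class] in tree-of-domains orientation (from
#'   [transposeCensus()]).
#' @param config search effort, see [searchConfig()].
#' @param seed RNG seed for the search.
#' @return A rooted \code{phylo} whose tips are fold families.
#' @export
buildTod <- function(mt, config = searchConfig(), seed = 1L) {
  stopifnot(is(mt, "CodedCensus"))
  if (mt@taxaAre != "families")
    stop("buildTod expects a transposed matrix (families as taxa); ",
         "use transposeCensus()", call. = FALSE)
  sr <- parsimonySearch(mt, config, seed)
  lundbergRoot(sr$tree, mt, ancestorState = stateCount(mt) - 1L)
}

#' Relative node-distance ages from a rooted tree of domains
#'
#' The age of each fold family is the number of internal nodes on the path
#' from the root to its leaf, rescaled to nd in [0, 1]: 0 for the leaf
#' closest to the root (most ancient) and 1 for the deepest leaf (most
#' recent). On a perfectly balanced tree all leaves are equidistant; the
#' degenerate all-zero result is returned with a warning.
#'
#' @param tod a rooted \code{phylo}.
#' @return Named numeric vector of nd values, one per leaf.
#' @export
nodeDistances <- function(tod) {
  .assertPhylo(tod)
  if (!ape::is.rooted(tod))
    stop("nodeDistances needs a rooted tree", call. = FALSE)
  tr <- tod
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  if (max(d) == min(d)) {
    warning("all leaves equidistant from the root; nd degenerate (all 0)",
            call. = FALSE)
    return(setNames(rep(0, length(d)), tod$tip.label))
  }
  setNames((d - min(d)) / (max(d) - min(d)), tod$tip.label)
}

#' Molecular clock of protein fold ages
#'
#' A linear map from relative age nd to geological age in gigayears before
#' present, fitted by least squares through calibration anchors. The
#' default anchors are (nd, Gy) = (0.15, 3.2), (0.26, 2.8) and
#' (0.55, 1.6) - the first archaeal loss, the first bacteria-specific
#' family and the joint archaeal/eukaryal diversification.
#'
#' @param anchors data.frame with columns \code{nd} and \code{age}.
#' @return A list of class \code{"foldClock"} with \code{intercept},
#'   \code{slope} (Gy lost per unit nd, positive) and the anchors.
#' @export
foldClock <- function(anchors = data.frame(nd = c(0.15, 0.26, 0.55),
                                           age = c(3.2, 2.8, 1.6))) {
  stopifnot(is.data.frame(anchors), all(c("nd", "age") %in% names(anchors)),
            nrow(anchors) >= 2L)
  fit <- lm(age ~ nd, data = anchors)
  slope <- -unname(coef(fit)[2L])
  if (!(slope > 0))
    stop("clock must be decreasing: age falls as nd grows", call. = FALSE)
  structure(list(intercept = unname(coef(fit)[1L]), slope = slope,
                 anchors = anchors), class = "foldClock")
}

#' Geological age from relative age
#'
#' Evaluates a [foldClock()]: \code{age = intercept - slope * nd},
#' clipped below at 0 Gy.
#'
#' @param nd numeric vector of relative ages in [0, 1].
#' @param clock a \code{foldClock}.
#' @return Ages in gigayears before present.
#' @export
calibrateAge <- function(nd, clock = foldClock()) {
  if (!inherits(clock, "foldClock"))
    stop("clock must be fitted with foldClock()", call. = FALSE)
  pmax(clock$intercept - clock$slope * nd, 0)
}

#' Assign evolutionary epochs
#'
#' Maps relative ages onto the three epochs with left-closed interval
#' semantics: early (0 <= nd < earlyEnd), intermediate
#' (earlyEnd <= nd < lateStart), late (lateStart <= nd <= 1).
#'
#' @param nd numeric vector in [0, 1].
#' @param epochs an [epochBoundaries()] list.
#' @return Factor with levels early, intermediate, late.
#' @export
assignEpoch <- function(nd, epochs = epochBoundaries()) {
  if (any(nd < 0 | nd > 1, na.rm = TRUE))
    stop("nd must lie in [0, 1]", call. = FALSE)
  out <- ifelse(nd < epochs$earlyEnd, "early",
                ifelse(nd < epochs$lateStart, "intermediate", "late"))
  factor(out, levels = c("early", "intermediate", "late"))
}

#' Distribution index (f-value) of each fold family
#'
#' The fraction of sampled proteomes encoding the family: 1 means complete
#' presence. All-zero columns cannot occur in a valid census, so f > 0.
#'
#' @param m a [DomainCensus-class].
#' @return Named numeric vector in (0, 1], one value per family.
#' @export
fValues <- function(m) {
  stopifnot(is(m, "DomainCensus"))
  colMeans(censusCounts(m) > 0L)
}

#' Venn (taxonomic group) classification of fold families
#'
#' Classifies every family by the set of superkingdoms in which at least
#' one proteome encodes it, written in A, B, E order (e.g. "AE" for
#' families present only in Archaea and Eukarya). The seven possible
#' groups partition the family set.
#'
#' @param m a [DomainCensus-class].
#' @return Named character vector of group labels, one per family; the
#'   per-group sizes are attached as attribute \code{"summary"} (see
#'   [vennTotals()] for per-superkingdom totals).
#' @export
vennClassify <- function(m) {
  stopifnot(is(m, "DomainCensus"))
  cnt <- censusCounts(m)
  sk <- superkingdoms(m)
  pres <- vapply(.SUPERKINGDOMS, function(s)
    colSums(cnt[sk == s, , drop = FALSE] > 0L) > 0L,
    logical(ncol(cnt)))
  if (ncol(cnt) == 1L) pres <- matrix(pres, 1L, 3L,
                                      dimnames = list(colnames(cnt),
                                                      .SUPERKINGDOMS))
  grp <- apply(pres, 1L, function(p) paste(.SUPERKINGDOMS[p], collapse = ""))
  groups <- c("A", "B", "E", "AB", "AE", "BE", "ABE")
  sizes <- setNames(vapply(groups, function(g) sum(grp == g), numeric(1)),
                    groups)
  attr(grp, "summary") <- sizes
  grp
}

#' Per-superkingdom totals from Venn group sizes
#'
#' The total number of families of a superkingdom is the sum of the sizes
#' of every Venn group whose label contains it (e.g. total(A) =
#' A + AB + AE + ABE).
#'
#' @param sizes named numeric vector of the seven group sizes (names among
#'   A, B, E, AB, AE, BE, ABE).
#' @return Named numeric vector of totals for A, B and E.
#' @examples
#' vennTotals(c(ABE = 484, BE = 414, AB = 90, AE = 40,
#'              A = 89, B = 522, E = 758))
#' @export
vennTotals <- function(sizes) {
  stopifnot(!is.null(names(sizes)))
  setNames(vapply(.SUPERKINGDOMS, function(s)
    sum(sizes[grepl(s, names(sizes), fixed = TRUE)]), numeric(1)),
    .SUPERKINGDOMS)
}

#' Persistence metrics of each proteome
#'
#' Economy is the number of distinct fold families encoded by a proteome,
#' flexibility the total (redundant) family abundance, and robustness the
#' ratio flexibility / economy. For non-empty proteomes
#' flexibility >= economy >= 1 and robustness >= 1.
#'
#' @param m a [DomainCensus-class].
#' @return A data.frame with one row per proteome: \code{proteome},
#'   \code{superkingdom}, \code{economy}, \code{flexibility},
#'   \code{robustness}.
#' @export
persistenceMetrics <- function(m) {
  stopifnot(is(m, "DomainCensus"))
  cnt <- censusCounts(m)
  eco <- rowSums(cnt > 0L)
  if (any(eco == 0L))
    stop("empty proteome row(s): ",
         paste(rownames(cnt)[eco == 0L], collapse = ", "), call. = FALSE)
  flex <- rowSums(cnt)
  data.frame(proteome = rownames(cnt),
             superkingdom = as.character(superkingdoms(m)),
             economy = as.integer(eco), flexibility = as.integer(flex),
             robustness = flex / eco,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the fold-family timeline table
#'
#' Joins the relative and geological ages with the distribution index and
#' Venn classification into one table, the package's counterpart of a
#' domain-age timeline report.
#'
#' @param m the [DomainCensus-class] the analysis started from.
#' @param tod a rooted tree of domains over the families of \code{m}.
#' @param clock a [foldClock()].
#' @param epochs an [epochBoundaries()] list.
#' @return A data.frame with columns \code{css}, \code{name}, \code{nd},
#'   \code{age_gy}, \code{epoch}, \code{f_value}, \code{venn_group},
#'   sorted by nd then css.
#' @export
buildTimeline <- function(m, tod, clock = foldClock(),
                          epochs = epochBoundaries()) {
  stopifnot(is(m, "DomainCensus"))
  nd <- nodeDistances(tod)
  ffs <- familyKeys(m)
  miss <- setdiff(ffs, names(nd))
  if (length(miss))
    stop("tree of domains lacks famil",
         if (length(miss) == 1L) "y: " else "ies: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  nd <- nd[ffs]
  fv <- fValues(m)
  grp <- vennClassify(m)
  nm <- m@ffNames[ffs]
  out <- data.frame(
    css = ffs,
    name = ifelse(is.na(nm), "", nm),
    nd = unname(nd),
    age_gy = unname(calibrateAge(nd, clock)),
    epoch = assignEpoch(unname(nd), epochs),
    f_value = unname(fv[ffs]),
    venn_group = unname(grp[ffs]),
    stringsAsFactors = FALSE)
  out <- out[order(out$nd, out$css), , drop = FALSE]
  rownames(out) <- NULL
  out
}
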