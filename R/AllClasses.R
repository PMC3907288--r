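#' @include utils.R
NULL

# Alphanumeric symbol set used for the 24-state abundance coding (0-9, A-N)
# and the binary occurrence coding.
.ABUNDANCE_SYMBOLS <- "0123456789ABCDEFGHIJKLMN"
.OCCURRENCE_SYMBOLS <- "01"

.SUPERKINGDOMS <- c("A", "B", "E")

#' DomainCensus: a proteome-by-fold-family abundance matrix
#'
#' Holds the raw genomic census: one row per proteome, one column per SCOP
#' fold family (FF, identified by its concise classification string, css),
#' with non-negative integer abundance counts \eqn{g_{ab}} (the number of
#' domains of that family detected in that proteome). Each proteome carries a
#' superkingdom label (A = Archaea, B = Bacteria, E = Eukarya). Columns that
#' are zero across all proteomes are disallowed; [readAssignmentTable()]
#' drops them with a warning when building the object.
#'
#' @slot counts integer matrix, proteomes x FFs, all entries >= 0, with
#'   unique row (proteome id) and column (css) names.
#' @slot superkingdom factor with levels A, B, E, one per proteome row.
#' @slot ffNames named character vector of free-text FF names (possibly
#'   empty), named by css.
#'
#' @seealso [readAssignmentTable()], [encodeAbundance()],
#'   [encodeOccurrence()], [fValues()], [vennClassify()],
#'   [persistenceMetrics()]
#' @export
setClass("DomainCensus",
  representation(counts = "matrix", superkingdom = "factor",
                 ffNames = "character"))

setValidity("DomainCensus", function(object) {
  cnt <- object@counts
  msg <- character()
  if ((nrow(cnt) > 0 && is.null(rownames(cnt))) ||
      (ncol(cnt) > 0 && is.null(colnames(cnt))))
    msg <- c(msg, "counts must have proteome row names and css column names")
  else {
    if (anyDuplicated(rownames(cnt)))
      msg <- c(msg, "duplicated proteome ids")
    if (anyDuplicated(colnames(cnt)))
      msg <- c(msg, "duplicated fold-family css")
    bad <- colnames(cnt)[!.isValidCss(colnames(cnt))]
    if (length(bad))
      msg <- c(msg, paste0("malformed css: ", paste(head(bad, 5), collapse = ", ")))
  }
  if (any(cnt < 0)) msg <- c(msg, "negative abundance counts")
  if (any(cnt != round(cnt))) msg <- c(msg, "non-integer abundance counts")
  if (ncol(cnt) > 0 && any(colSums(cnt) == 0))
    msg <- c(msg, "all-zero fold-family columns are not allowed")
  if (length(object@superkingdom) != nrow(cnt))
    msg <- c(msg, "one superkingdom label required per proteome")
  if (!all(levels(object@superkingdom) %in% .SUPERKINGDOMS))
    msg <- c(msg, "superkingdom labels must be A, B or E")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainCensus from a count matrix
#'
#' @param counts numeric matrix of non-negative integer abundance counts with
#'   proteome ids as row names and SCOP css as column names.
#' @param superkingdom character or factor of superkingdom labels
#'   (\code{"A"}, \code{"B"}, \code{"E"}), one per row of \code{counts}.
#' @param ffNames optional named character vector of free-text family names,
#'   named by css.
#' @return A [DomainCensus-class] object with rows sorted by proteome id and
#'   columns by css, so downstream outputs are deterministic.
#' @examples
#' m <- matrix(c(5, 2, 1, 0), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("c.37.1.12", "d.122.1.1")))
#' DomainCensus(m, c("A", "B"))
#' @export
DomainCensus <- function(counts, superkingdom, ffNames = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  superkingdom <- factor(as.character(superkingdom), levels = .SUPERKINGDOMS)
  if (anyNA(superkingdom))
    stop("superkingdom labels must be one of A, B, E", call. = FALSE)
  ord_p <- order(rownames(counts))
  ord_f <- order(colnames(counts))
  counts <- counts[ord_p, ord_f, drop = FALSE]
  superkingdom <- superkingdom[ord_p]
  names(superkingdom) <- rownames(counts)
  new("DomainCensus", counts = counts, superkingdom = superkingdom,
      ffNames = ffNames)
}

#' CodedCensus: an ordered multistate character matrix
#'
#' The character-coded form of a [DomainCensus-class]: every cell holds an
#' ordered integer state in \code{0..(k-1)}. The abundance model uses k = 24
#' states written with the alphanumeric alphabet \code{"0123...KLMN"}; the
#' occurrence (presence/absence) model uses k = 2 and alphabet \code{"01"}.
#' In the tree-of-life orientation rows are proteomes (taxa) and columns are
#' fold families (characters); [transposeCensus()] flips to the
#' tree-of-domains orientation where fold families are the taxa.
#'
#' @slot states integer matrix of character states in \code{0..(k-1)}.
#' @slot k integer state count (24 abundance, 2 occurrence).
#' @slot symbols single string: the on-disk alphabet, \code{symbols[i+1]}
#'   being the symbol of state \code{i}.
#' @slot model \code{"abundance"} or \code{"occurrence"}.
#' @slot taxaAre \code{"proteomes"} (tree-of-life orientation) or
#'   \code{"families"} (tree-of-domains orientation).
#' @slot superkingdom factor of superkingdom labels for the proteome axis,
#'   named by proteome id (kept through transposition).
#'
#' @seealso [encodeAbundance()], [encodeOccurrence()], [transposeCensus()],
#'   [writeCharacterMatrix()], [parsimonySearch()]
#' @export
setClass("CodedCensus",
  representation(states = "matrix", k = "integer", symbols = "character",
                 model = "character", taxaAre = "character",
                 superkingdom = "factor"))

setValidity("CodedCensus", function(object) {
  msg <- character()
  st <- object@states
  k <- object@k
  if (length(k) != 1L || k < 2L) msg <- c(msg, "k must be a single integer >= 2")
  if (any(st < 0L) || any(st >= k)) msg <- c(msg, "states must lie in 0..(k-1)")
  if (nchar(object@symbols) != k) msg <- c(msg, "symbol alphabet length must equal k")
  if (!object@model %in% c("abundance", "occurrence"))
    msg <- c(msg, "model must be 'abundance' or 'occurrence'")
  if (object@model == "abundance" && object@symbols != .ABUNDANCE_SYMBOLS)
    msg <- c(msg, "abundance alphabet must be '0123456789ABCDEFGHIJKLMN'")
  if (object@model == "occurrence" && object@symbols != .OCCURRENCE_SYMBOLS)
    msg <- c(msg, "occurrence alphabet must be '01'")
  if (!object@taxaAre %in% c("proteomes", "families"))
    msg <- c(msg, "taxaAre must be 'proteomes' or 'families'")
  if (is.null(rownames(st)) || is.null(colnames(st)))
    msg <- c(msg, "states must carry dimnames")
  if (length(msg)) msg else TRUE
})

.newCodedCensus <- function(states, k, symbols, model, taxaAre, superkingdom) {
  storage.mode(states) <- "integer"
  new("CodedCensus", states = states, k = as.integer(k), symbols = symbols,
      model = model, taxaAre = taxaAre, superkingdom = superkingdom)
}

## ------------------------------------------------------------------ ##
## Generics and accessors
## ------------------------------------------------------------------ ##

#' @describeIn DomainCensus-class raw abundance count matrix.
#' @param object,x a \code{DomainCensus} or \code{CodedCensus}.
#' @export
setGeneric("censusCounts", function(object) standardGeneric("censusCounts"))
#' @export
setMethod("censusCounts", "DomainCensus", function(object) object@counts)

#' @describeIn DomainCensus-class superkingdom labels, named by proteome id.
#' @export
setGeneric("superkingdoms", function(object) standardGeneric("superkingdoms"))
#' @export
setMethod("superkingdoms", "DomainCensus", function(object) object@superkingdom)
#' @export
setMethod("superkingdoms", "CodedCensus", function(object) object@superkingdom)

#' @describeIn DomainCensus-class proteome identifiers.
#' @export
setGeneric("proteomeIds", function(object) standardGeneric("proteomeIds"))
#' @export
setMethod("proteomeIds", "DomainCensus", function(object) rownames(object@counts))
#' @export
setMethod("proteomeIds", "CodedCensus", function(object)
  if (object@taxaAre == "proteomes") rownames(object@states) else colnames(object@states))

#' @describeIn DomainCensus-class fold-family css identifiers.
#' @export
setGeneric("familyKeys", function(object) standardGeneric("familyKeys"))
#' @export
setMethod("familyKeys", "DomainCensus", function(object) colnames(object@counts))
#' @export
setMethod("familyKeys", "CodedCensus", function(object)
  if (object@taxaAre == "proteomes") colnames(object@states) else rownames(object@states))

#' @describeIn DomainCensus-class global maximum abundance count
#'   \eqn{g_{max}} over the whole matrix.
#' @export
setGeneric("gMax", function(object) standardGeneric("gMax"))
#' @export
setMethod("gMax", "DomainCensus", function(object)
  if (length(object@counts)) max(object@counts) else 0L)

#' @describeIn CodedCensus-class integer state matrix.
#' @export
setGeneric("codedStates", function(object) standardGeneric("codedStates"))
#' @export
setMethod("codedStates", "CodedCensus", function(object) object@states)

#' @describeIn CodedCensus-class number of states k.
#' @export
setGeneric("stateCount", function(object) standardGeneric("stateCount"))
#' @export
setMethod("stateCount", "CodedCensus", function(object) object@k)

#' @describeIn CodedCensus-class on-disk symbol alphabet.
#' @export
setGeneric("stateSymbols", function(object) standardGeneric("stateSymbols"))
#' @export
setMethod("stateSymbols", "CodedCensus", function(object) object@symbols)

#' @describeIn CodedCensus-class coding model ("abundance" or "occurrence").
#' @export
setGeneric("codingModel", function(object) standardGeneric("codingModel"))
#' @export
setMethod("codingModel", "CodedCensus", function(object) object@model)

#' @export
setMethod("dim", "DomainCensus", function(x) dim(x@counts))
#' @export
setMethod("dim", "CodedCensus", function(x) dim(x@states))

setMethod("show", "DomainCensus", function(object) {
  tab <- table(object@superkingdom)
  cat("DomainCensus:", nrow(object@counts), "proteomes x",
      ncol(object@counts), "fold families\n")
  cat("  superkingdoms: A =", tab[["A"]], " B =", tab[["B"]],
      " E =", tab[["E"]], "\n")
  cat("  g_max =", gMax(object), "\n")
})

setMethod("show", "CodedCensus", function(object) {
  cat("CodedCensus (", object@model, " model, k = ", object@k, "): ",
      nrow(object@states), " taxa (", object@taxaAre, ") x ",
      ncol(object@states), " characters\n", sep = "")
  cat("  symbols: ", object@symbols, "\n", sep = "")
})
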