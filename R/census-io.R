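#' Read a fold-family assignment table into a DomainCensus
#'
#' Reads a tab-separated assignment table in the dialect produced by domain
#' census scans (one row per proteome/fold-family pair) and assembles the
#' proteome-by-FF abundance matrix. Required header columns:
#' \code{proteome_id}, \code{superkingdom} (A/B/E), \code{css} (SCOP concise
#' classification string) and \code{count} (non-negative integer abundance).
#' Duplicate (proteome, css) rows are summed. Fold families with zero total
#' abundance are dropped with a warning. Rows and columns of the result are
#' sorted (by proteome id and css) so downstream outputs are deterministic.
#'
#' @param path path to a tab-separated file with the four required columns.
#' @return A [DomainCensus-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("proteome_id\tsuperkingdom\tcss\tcount",
#'              "p1\tA\tc.37.1.12\t5",
#'              "p1\tA\td.122.1.1\t1",
#'              "p2\tB\tc.37.1.12\t2"), tf)
#' readAssignmentTable(tf)
#' @export
readAssignmentTable <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("proteome_id", "superkingdom", "css", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("assignment table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  count <- suppressWarnings(as.numeric(tab$count))
  if (anyNA(count) || any(count != round(count))) {
    stop("column 'count' must hold integers", call. = FALSE)
  }
  if (any(count < 0)) stop("negative counts are not allowed", call. = FALSE)
  bad_sk <- setdiff(unique(tab$superkingdom), .SUPERKINGDOMS)
  if (length(bad_sk)) {
    stop("superkingdom labels outside {A, B, E}: ",
         paste(bad_sk, collapse = ", "), call. = FALSE)
  }
  bad_css <- unique(tab$css[!.isValidCss(tab$css)])
  if (length(bad_css)) {
    stop("malformed SCOP css: ", paste(head(bad_css, 5), collapse = ", "),
         call. = FALSE)
  }
  sk_by_p <- tapply(tab$superkingdom, tab$proteome_id,
                    function(x) unique(x))
  multi <- names(sk_by_p)[lengths(sk_by_p) > 1L]
  if (length(multi)) {
    stop("conflicting superkingdom labels for proteome(s): ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  prot <- sort(unique(tab$proteome_id))
  ffs <- sort(unique(tab$css))
  cnt <- matrix(0L, length(prot), length(ffs), dimnames = list(prot, ffs))
  agg <- tapply(count, list(tab$proteome_id, tab$css), sum)
  cnt[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0L, as.integer(agg))
  zero <- colSums(cnt) == 0L
  if (any(zero)) {
    warning("dropping ", sum(zero), " fold famil",
            if (sum(zero) == 1L) "y" else "ies",
            " with zero total abundance: ",
            paste(head(colnames(cnt)[zero], 5), collapse = ", "),
            call. = FALSE)
    cnt <- cnt[, !zero, drop = FALSE]
  }
  DomainCensus(cnt, vapply(prot, function(p) sk_by_p[[p]], character(1)))
}

#' Log-rescale abundance counts into ordered multistate characters
#'
#' Recodes raw abundance counts \eqn{g_{ab}} into k ordered states (default
#' k = 24, symbols 0-9 and A-N) by
#' \deqn{state = round\left(\frac{\ln(g_{ab}+1)}{\ln(g_{max}+1)} (k-1)\right)}
#' where \eqn{g_{max}} is the single global maximum of the matrix. The +1
#' offset pins zero abundance exactly to state 0, as required by the
#' 0-ancestral polarization of the trees of life; the maximum count maps to
#' state k-1. The logarithm base is immaterial (the ratio is base
#' invariant). Rounding is half-away-from-zero. The coding is monotone
#' non-decreasing in \eqn{g_{ab}}.
#'
#' @param m a [DomainCensus-class].
#' @param k number of ordered states (scaling constant + 1); the default 24
#'   matches the alphanumeric 0-N alphabet.
#' @return A [CodedCensus-class] in tree-of-life orientation
#'   (proteomes as taxa).
#' @examples
#' m <- DomainCensus(matrix(c(0L, 7L, 1000L, 1L), 2, 2,
#'        dimnames = list(c("p1", "p2"), c("a.1.1.1", "b.1.1.1"))),
#'        c("A", "B"))
#' codedStates(encodeAbundance(m))
#' @export
encodeAbundance <- function(m, k = 24L) {
  stopifnot(is(m, "DomainCensus"))
  k <- as.integer(k)
  if (k != 24L && k != nchar(.ABUNDANCE_SYMBOLS))
    stop("abundance coding uses the fixed 24-symbol alphabet", call. = FALSE)
  gmax <- gMax(m)
  if (gmax < 1L) stop("empty census: g_max must be >= 1", call. = FALSE)
  cnt <- censusCounts(m)
  st <- .roundHalfAway(log(cnt + 1) / log(gmax + 1) * (k - 1L))
  storage.mode(st) <- "integer"
  .newCodedCensus(st, k, .ABUNDANCE_SYMBOLS, "abundance", "proteomes",
                  superkingdoms(m))
}

#' Binary presence/absence character coding
#'
#' Codes each cell as state 1 when the fold family is present
#' (\eqn{g_{ab} > 0}) and 0 when absent.
#'
#' @param m a [DomainCensus-class].
#' @return A [CodedCensus-class] with k = 2 in tree-of-life orientation.
#' @export
encodeOccurrence <- function(m) {
  stopifnot(is(m, "DomainCensus"))
  st <- (censusCounts(m) > 0L) + 0L
  storage.mode(st) <- "integer"
  .newCodedCensus(st, 2L, .OCCURRENCE_SYMBOLS, "occurrence", "proteomes",
                  superkingdoms(m))
}

#' Transpose a coded matrix between tree-of-life and tree-of-domains
#' orientation
#'
#' Swaps the axes of a [CodedCensus-class] so fold families become the taxa
#' and proteomes the characters (or back). States are unchanged; the
#' operation is an involution.
#'
#' @param m a [CodedCensus-class].
#' @return The transposed [CodedCensus-class].
#' @export
transposeCensus <- function(m) {
  stopifnot(is(m, "CodedCensus"))
  .newCodedCensus(t(m@states), m@k, m@symbols, m@model,
                  if (m@taxaAre == "proteomes") "families" else "proteomes",
                  m@superkingdom)
}

# symbol <-> state maps over the alphabet of a coded matrix
.stateToSymbol <- function(states, symbols) {
  strsplit(symbols, "")[[1]][states + 1L]
}

.symbolToState <- function(chars, symbols) {
  st <- match(toupper(chars), strsplit(symbols, "")[[1]]) - 1L
  st[chars == "?"] <- 0L  # missing data read as absence; never written
  if (anyNA(st)) {
    stop("symbols outside the declared alphabet: ",
         paste(unique(chars[is.na(st)]), collapse = " "), call. = FALSE)
  }
  st
}
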