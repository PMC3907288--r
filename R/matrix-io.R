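# Character-matrix serialization: NEXUS DATA blocks and relaxed PHYLIP for
# multistate symbol alphabets, plus a TSV dump. ape/phangorn readers target
# molecular alphabets, so the multistate dialect used here (arbitrary
# SYMBOLS lists, single-character states) is written and parsed directly.

.sanitizeLabel <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)

.matrixLabels <- function(m) {
  lab <- .sanitizeLabel(rownames(m@states))
  dup <- unique(lab[duplicated(lab)])
  if (length(dup)) {
    stop("taxon labels collide after sanitization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  lab
}

#' Write a coded character matrix to NEXUS or PHYLIP
#'
#' Serializes a [CodedCensus-class] for parsimony software. The NEXUS DATA
#' block declares NTAX, NCHAR and a SYMBOLS list equal to the matrix
#' alphabet (\code{"0123456789ABCDEFGHIJKLMN"} for abundance, \code{"01"}
#' for occurrence). The PHYLIP dialect is relaxed: a header line
#' \code{ntax nchar} followed by \code{label<TAB>states}. Taxon labels are
#' sanitized to \code{[A-Za-z0-9_.]}; collisions after sanitization are an
#' error. Files re-read with [readCharacterMatrix()] reproduce the state
#' matrix exactly.
#'
#' @param m a [CodedCensus-class].
#' @param path output file path.
#' @param format \code{"nexus"} (default) or \code{"phylip"}.
#' @return \code{path}, invisibly.
#' @export
writeCharacterMatrix <- function(m, path, format = c("nexus", "phylip")) {
  stopifnot(is(m, "CodedCensus"))
  format <- match.arg(format)
  lab <- .matrixLabels(m)
  rows <- vapply(seq_len(nrow(m@states)), function(i) {
    paste(.stateToSymbol(m@states[i, ], m@symbols), collapse = "")
  }, character(1))
  if (format == "nexus") {
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m@states), ncol(m@states)),
      sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=?;", m@symbols),
      "  MATRIX",
      sprintf("    %s  %s", formatC(lab, width = max(nchar(lab)), flag = "-"), rows),
      "  ;",
      "END;")
  } else {
    lines <- c(sprintf("%d %d", nrow(m@states), ncol(m@states)),
               paste0(lab, "\t", rows))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a coded character matrix written by writeCharacterMatrix
#'
#' The coding model is inferred from the symbol alphabet (\code{"01"} is
#' occurrence, the 24-symbol alphanumeric alphabet is abundance). A
#' \code{"?"} state is accepted on input and treated as absence (state 0);
#' it is never emitted on write.
#'
#' @param path file path.
#' @param format \code{"nexus"} or \code{"phylip"}.
#' @param taxaAre orientation of the stored matrix, \code{"proteomes"}
#'   (default) or \code{"families"}; serialized files do not record it.
#' @param superkingdom optional factor of superkingdom labels for the
#'   proteome axis (lost on serialization).
#' @return A [CodedCensus-class].
#' @export
readCharacterMatrix <- function(path, format = c("nexus", "phylip"),
                                taxaAre = c("proteomes", "families"),
                                superkingdom = factor(levels = .SUPERKINGDOMS)) {
  format <- match.arg(format)
  taxaAre <- match.arg(taxaAre)
  lines <- readLines(path)
  if (format == "nexus") {
    if (!grepl("^#NEXUS", lines[1], ignore.case = TRUE))
      stop("not a NEXUS file: ", path, call. = FALSE)
    fmt <- grep("FORMAT", lines, ignore.case = TRUE, value = TRUE)
    sym <- sub(".*SYMBOLS=\"([^\"]+)\".*", "\\1", fmt[1])
    i0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
    i1 <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > i0)[1]
    body <- trimws(lines[(i0 + 1):(i1 - 1)])
  } else {
    hdr <- scan(text = lines[1], quiet = TRUE)
    body <- trimws(lines[-1])
    body <- body[nzchar(body)]
    if (length(body) != hdr[1])
      stop("PHYLIP header declares ", hdr[1], " taxa, found ", length(body),
           call. = FALSE)
    sym <- NULL
  }
  body <- body[nzchar(body)]
  parts <- regmatches(body, regexpr("\\S+", body))
  rows <- sub("^\\S+\\s+", "", body)
  rows <- gsub("\\s", "", rows)
  if (is.null(sym)) {
    sym <- if (all(strsplit(paste(rows, collapse = ""), "")[[1]] %in% c("0", "1", "?")))
      .OCCURRENCE_SYMBOLS else .ABUNDANCE_SYMBOLS
  }
  sym <- toupper(sym)
  model <- if (sym == .OCCURRENCE_SYMBOLS) "occurrence" else "abundance"
  st <- do.call(rbind, lapply(rows, function(r)
    .symbolToState(strsplit(r, "")[[1]], sym)))
  dimnames(st) <- list(parts, NULL)
  colnames(st) <- paste0("char", seq_len(ncol(st)))
  .newCodedCensus(st, nchar(sym), sym, model, taxaAre, superkingdom)
}

#' Dump a coded matrix as TSV
#'
#' Writes taxa x characters integer states with row and column names, a
#' convenient exchange format for inspection outside phylogenetic software.
#'
#' @param m a [CodedCensus-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCodedTsv <- function(m, path) {
  stopifnot(is(m, "CodedCensus"))
  df <- data.frame(taxon = rownames(m@states), m@states,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
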