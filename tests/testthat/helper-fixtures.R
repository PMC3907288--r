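# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

skFactor <- function(x) factor(x, levels = c("A", "B", "E"))

# A CodedCensus straight from a state matrix (rows taxa, cols characters).
makeCoded <- function(states, model = c("abundance", "occurrence"),
                      sk = NULL, taxaAre = "proteomes") {
  model <- match.arg(model)
  k <- if (model == "abundance") 24L else 2L
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("a.%d.1.1", seq_len(ncol(states)))
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("t%02d", seq_len(nrow(states)))
  if (is.null(sk)) sk <- rep("A", nrow(states))
  symbols <- if (k == 24L) "0123456789ABCDEFGHIJKLMN" else "01"
  domtrace:::.newCodedCensus(states, k, symbols, model, taxaAre,
                             setNames(skFactor(sk), rownames(states)))
}

# Single-character coded matrix from a named integer vector of leaf states.
makeChar <- function(x, model = "abundance") {
  makeCoded(matrix(x, ncol = 1, dimnames = list(names(x), "a.1.1.1")),
            model = model)
}

# A small census with all three superkingdoms.
makeCensus <- function(counts, sk) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("b.%d.1.1", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("p%02d", seq_len(nrow(counts)))
  DomainCensus(counts, sk)
}

# Write an assignment TSV from long-format rows.
writeAssignmentFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("proteome_id\tsuperkingdom\tcss\tcount",
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# Perfectly compatible binary matrix encoding the internal splits of a tree
# (each internal edge contributes `dup` identical presence characters).
splitMatrix <- function(tree, dup = 3L) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  root <- E[nrow(E), 1L]
  cols <- list()
  for (v in unique(E[, 2L])) {
    if (v <= ntip || v == root) next
    below <- ape::extract.clade(po, v)$tip.label
    x <- setNames(as.integer(tree$tip.label %in% below), tree$tip.label)
    for (d in seq_len(dup)) cols[[length(cols) + 1L]] <- x
  }
  S <- do.call(cbind, cols)
  rownames(S) <- tree$tip.label
  colnames(S) <- sprintf("a.%d.1.1", seq_len(ncol(S)))
  S
}
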