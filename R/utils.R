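# Internal helpers shared across modules.

# Round half away from zero (so state 0.5 -> 1), centralized so the coding
# rule can be swapped in one place. base::round() rounds half to even, which
# is not what multistate recoding wants.
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Column minima of a small-row matrix without apply() overhead.
.colMins <- function(m) {
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) out <- pmin(out, m[i, ])
  out
}

# Validate the SCOP concise classification string "x.F.S.f".
.isValidCss <- function(css) {
  grepl("^[a-g]\\.[0-9]+\\.[0-9]+\\.[0-9]+$", css)
}

# Deterministic derivation of per-stage seeds from one global seed, kept
# below 2^31 - 1.
.deriveSeed <- function(seed, stage) {
  offs <- c(census = 11L, tree = 101L, bootstrap = 211L, gainloss = 307L,
            tod = 401L, compare = 503L, simulate = 601L, sampling = 701L)
  stopifnot(stage %in% names(offs))
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

.assertPhylo <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be an object of class \"phylo\"", call. = FALSE)
  }
  invisible(tree)
}

# Leaf set / matrix taxa agreement, reporting the symmetric difference.
.assertLeafMatch <- function(tree, taxa) {
  only_tree <- setdiff(tree$tip.label, taxa)
  only_mat <- setdiff(taxa, tree$tip.label)
  if (length(only_tree) || length(only_mat)) {
    stop("tree leaves and matrix taxa disagree; only in tree: {",
         paste(only_tree, collapse = ", "), "}; only in matrix: {",
         paste(only_mat, collapse = ", "), "}", call. = FALSE)
  }
  invisible(TRUE)
}
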