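# End-to-end orchestration: census -> coding -> tree search -> Lundberg
# rooting -> ancestral reconstruction -> gain/loss tallies -> timeline ->
# tree comparison -> report tables. The R functions (and this driver) are
# the package's interface; every stage communicates through the declared
# classes and file formats only.

#' Pipeline configuration
#'
#' @param model coding model(s) to run: \code{"abundance"},
#'   \code{"occurrence"} or \code{"both"}.
#' @param epochs an [epochBoundaries()] list.
#' @param search a [searchConfig()] for the trees of life.
#' @param todSearch a [searchConfig()] for the trees of domains (often
#'   lighter: ToDs have one taxon per fold family).
#' @param policy ancestral-state tie policy, see [ancestralStates()].
#' @param bootstrap bootstrap replicates for the tree of life (0 skips).
#' @param clock a [foldClock()].
#' @param seed single global seed; per-stage seeds are derived from it
#'   deterministically so stages are independently reproducible.
#' @param tree optional fixed taxon tree (rooted or unrooted); when given,
#'   the tree search is skipped and gain/loss tracing runs on this
#'   topology.
#' @param superkingdomRatios compute per-superkingdom pruned-tree ratio
#'   summaries (requires >= 4 taxa in a superkingdom to include it).
#' @return A list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(model = c("both", "abundance", "occurrence"),
                           epochs = epochBoundaries(),
                           search = searchConfig(),
                           todSearch = searchConfig(nStarts = 1L,
                                                    maxSweeps = 2L),
                           policy = "closest",
                           bootstrap = 0L,
                           clock = foldClock(),
                           seed = 1L,
                           tree = NULL,
                           superkingdomRatios = TRUE) {
  model <- match.arg(model)
  structure(list(model = model, epochs = epochs, search = search,
                 todSearch = todSearch, policy = policy,
                 bootstrap = as.integer(bootstrap), clock = clock,
                 seed = as.integer(seed), tree = tree,
                 superkingdomRatios = isTRUE(superkingdomRatios)),
            class = "pipelineConfig")
}

.runModel <- function(census, coded, cfg) {
  if (!is.null(cfg$tree)) {
    tol <- cfg$tree
    if (!ape::is.rooted(tol)) tol <- lundbergRoot(tol, coded, 0L)
    search_len <- wagnerLength(tol, coded)$total
  } else {
    sr <- parsimonySearch(coded, cfg$search, seed = .deriveSeed(cfg$seed, "tree"))
    tol <- lundbergRoot(sr$tree, coded, 0L)
    search_len <- sr$length
  }
  rec <- ancestralStates(tol, coded, policy = cfg$policy, rootState = 0L)
  events <- traceChanges(rec)
  records <- tallyGainLoss(events)
  mt <- transposeCensus(coded)
  tod <- buildTod(mt, cfg$todSearch, seed = .deriveSeed(cfg$seed, "tod"))
  nd <- nodeDistances(tod)
  summary <- ratioSummary(records, ndMap = nd, epochs = cfg$epochs)
  timeline <- buildTimeline(census, tod, clock = cfg$clock,
                            epochs = cfg$epochs)
  sk_sum <- NULL
  if (cfg$superkingdomRatios) {
    sk_tab <- table(superkingdoms(coded))
    sk_sum <- lapply(setNames(nm = .SUPERKINGDOMS), function(s) {
      if (sk_tab[[s]] < 4L) return(NULL)
      superkingdomAnalysis(coded, tol, s, policy = cfg$policy,
                           ndMap = nd, epochs = cfg$epochs)
    })
  }
  support <- NULL
  if (cfg$bootstrap > 0L) {
    support <- bootstrapSupport(coded, tol, cfg$bootstrap,
                                seed = .deriveSeed(cfg$seed, "bootstrap"))
  }
  list(coded = coded, tol = tol, treeLength = search_len,
       reconstruction = rec, events = events, records = records,
       summary = summary, tod = tod, nd = nd, timeline = timeline,
       superkingdoms = sk_sum, bootstrap = support)
}

#' Run the full gain/loss analysis pipeline
#'
#' Executes the analysis end to end for one or both coding models and
#' bundles every artifact: coded matrices, rooted trees of life and of
#' domains, ancestral reconstructions, per-family gain/loss records,
#' ratio summaries (global, per superkingdom, per epoch), the fold-family
#' timeline, and (in "both" mode) the abundance/occurrence tree
#' comparison and consensus gained/lost sets. Rerunning with the same
#' configuration reproduces the bundle exactly.
#'
#' @param input a [DomainCensus-class] or the path of an assignment table
#'   for [readAssignmentTable()].
#' @param config a [pipelineConfig()].
#' @return A list of class \code{"domtracePipeline"}.
#' @export
runPipeline <- function(input, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  census <- if (is(input, "DomainCensus")) input else readAssignmentTable(input)
  models <- if (config$model == "both") c("abundance", "occurrence") else config$model
  bundle <- list(census = census, config = config,
                 persistence = persistenceMetrics(census),
                 venn = vennClassify(census),
                 fValues = fValues(census),
                 models = list())
  for (mod in models) {
    coded <- if (mod == "abundance") encodeAbundance(census) else
      encodeOccurrence(census)
    bundle$models[[mod]] <- .runModel(census, coded, config)
  }
  if (length(models) == 2L) {
    bundle$comparison <- guidedRandomizationTest(
      bundle$models$abundance$tol, bundle$models$occurrence$tol,
      reps = 100L, seed = config$seed)
    bundle$consensus <- consensusSets(bundle$models$abundance$records,
                                      bundle$models$occurrence$records)
  }
  class(bundle) <- "domtracePipeline"
  bundle
}

#' @export
print.domtracePipeline <- function(x, ...) {
  cat("domtrace pipeline bundle:", nrow(censusCounts(x$census)),
      "proteomes x", ncol(censusCounts(x$census)), "fold families\n")
  for (mod in names(x$models)) {
    s <- x$models[[mod]]$summary
    cat(sprintf("  %-10s tree length %d; %d gains vs %d losses (ratio %s)\n",
                mod, x$models[[mod]]$treeLength, s$totalGains, s$totalLosses,
                if (is.na(s$ratio)) "inf" else format(round(s$ratio, 2))))
  }
  if (!is.null(x$comparison))
    cat("  abundance vs occurrence ToL nodal RMSD:",
        format(round(x$comparison$rmsd, 3)), "\n")
  invisible(x)
}

#' Write pipeline report tables
#'
#' Emits the per-family gain/loss TSV for each model (name, css, gains,
#' losses, net, class), the timeline TSV, the Venn group summary, the
#' persistence table, the per-epoch ratio table and a JSON summary with
#' totals, ratios and the tie policy and seed used.
#'
#' @param bundle a \code{domtracePipeline} from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
reportTables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "domtracePipeline"))
  need <- c("census", "models", "persistence", "venn")
  miss <- need[!need %in% names(bundle)]
  if (length(miss) || !length(bundle$models))
    stop("incomplete bundle; missing: ",
         paste(c(miss, if (!length(bundle$models)) "models"), collapse = ", "),
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  nm <- bundle$census@ffNames
  for (mod in names(bundle$models)) {
    mm <- bundle$models[[mod]]
    rec <- mm$records
    out <- data.frame(name = ifelse(is.na(nm[rec$css]), "", nm[rec$css]),
                      css = rec$css, gains = rec$gains, losses = rec$losses,
                      net = rec$net, class = rec$class,
                      stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("gain_loss_%s.tsv", mod))
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[paste0("gain_loss_", mod)] <- f
    f <- file.path(dir, sprintf("timeline_%s.tsv", mod))
    write.table(mm$timeline, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[paste0("timeline_", mod)] <- f
    f <- file.path(dir, sprintf("epoch_ratios_%s.tsv", mod))
    write.table(mm$summary$perEpoch, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[paste0("epoch_ratios_", mod)] <- f
    f <- file.path(dir, sprintf("tol_%s.nwk", mod))
    ape::write.tree(mm$tol, f)
    files[paste0("tol_", mod)] <- f
    f <- file.path(dir, sprintf("tod_%s.nwk", mod))
    ape::write.tree(mm$tod, f)
    files[paste0("tod_", mod)] <- f
  }
  venn_sizes <- attr(bundle$venn, "summary")
  f <- file.path(dir, "venn_summary.tsv")
  write.table(data.frame(group = names(venn_sizes),
                         n_families = as.integer(venn_sizes)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["venn_summary"] <- f
  f <- file.path(dir, "persistence.tsv")
  write.table(bundle$persistence, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["persistence"] <- f
  summ <- list(seed = bundle$config$seed, policy = bundle$config$policy,
               models = lapply(bundle$models, function(mm) {
                 list(treeLength = mm$treeLength,
                      totalGains = mm$summary$totalGains,
                      totalLosses = mm$summary$totalLosses,
                      ratio = mm$summary$ratio)
               }))
  if (!is.null(bundle$comparison)) {
    summ$comparison <- list(rmsd = bundle$comparison$rmsd,
                            randomMean = bundle$comparison$randomMean,
                            empiricalP = bundle$comparison$empiricalP)
  }
  if (!is.null(bundle$consensus)) summ$consensus <- bundle$consensus
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA)
  files["summary"] <- f
  invisible(files)
}
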