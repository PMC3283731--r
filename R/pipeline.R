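#' End-to-end alignment diagnostics pipeline
#'
#' Runs the full diagnostic battery on one alignment: treatment
#' application, composition summary, entropy profile and heterogeneity,
#' high-entropy runs, OTU clustering at a series of cutoffs with diversity
#' indices, substitution-saturation profiling, NJ tree construction and
#' the OTU distance-area table at the loosest cutoff. Returns a manifest
#' (a plain nested list) with every summary statistic; the manifest is
#' deterministic given the seed.
#'
#' @param aln a [SeqAlignment-class] (treatment T1).
#' @param treatments subset of \code{c("T1", "T2", "T3")} to analyse.
#' @param mask column mask for T3 (an \code{IRanges}); when \code{NULL} and
#'   T3 is requested, [detectAmbiguousColumns()] supplies one.
#' @param cutoffs OTU identity cutoffs, default
#'   \code{c(0.95, 0.97, 0.98, 0.99)}.
#' @param hMaxMode passed to [heterogeneitySummary()].
#' @param psiMode passed to [clusterOTUs()].
#' @param rodaMode passed to [distanceAreaTable()].
#' @param bootstrapReplicates NJ bootstrap pseudoreplicates (0 disables).
#' @param seed master seed; all randomness derives from it.
#' @return nested list manifest; see the package vignette for the layout.
#' @export
runPipeline <- function(aln, treatments = c("T1", "T2"), mask = NULL,
                        cutoffs = c(0.95, 0.97, 0.98, 0.99),
                        hMaxMode = "occurring_states", psiMode = "global",
                        rodaMode = "sum_internal",
                        bootstrapReplicates = 0L, seed = 1L) {
  stopifnot(is(aln, "SeqAlignment"))
  treatments <- match.arg(treatments, c("T1", "T2", "T3"), several.ok = TRUE)
  manifest <- list(
    seed = seed,
    nSequences = nrow(alignmentMatrix(aln)),
    treatments = list())
  for (tr in treatments) {
    a <- switch(tr,
      T1 = aln,
      T2 = applyT2(aln),
      T3 = applyT3(aln, if (is.null(mask)) detectAmbiguousColumns(aln) else mask))
    prof <- entropyProfile(a)
    het <- heterogeneitySummary(prof, hMaxMode = hMaxMode)
    runs <- highEntropyRuns(prof)
    comp <- compositionSummary(a)
    otuStats <- lapply(cutoffs, function(co) {
      tab <- classifyOTUs(clusterOTUs(a, co, psiMode = psiMode), a)
      div <- diversityIndices(otuSizes(tab))
      c(list(cutoff = co,
             singletons = sum(otuClasses(tab) == "singleton"),
             quasiSingletons = sum(otuClasses(tab) == "quasi_singleton")),
        div)
    })
    names(otuStats) <- sprintf("cutoff_%g", cutoffs)
    sat <- tryCatch(saturationProfile(a), error = function(e) NULL)
    treeBlock <- NULL
    km <- tryCatch(k2pMatrix(a), error = function(e) NULL)
    if (!is.null(km) && !anyNA(distMatrix(km)) && nrow(distMatrix(km)) >= 3) {
      if (bootstrapReplicates > 0) {
        bs <- bootstrapSupports(a, replicates = bootstrapReplicates,
                                seed = deriveSeed(seed, 1L))
        tree <- bs$tree
        treeBlock <- list(newick = ape::write.tree(tree),
                          meanSupport = mean(bs$supports),
                          nSupportsOver49 = sum(bs$supports > 49))
      } else {
        tree <- buildNJTree(km)
        treeBlock <- list(newick = ape::write.tree(tree))
      }
      tabLoose <- classifyOTUs(clusterOTUs(a, cutoffs[1], psiMode = psiMode), a)
      da <- distanceAreaTable(tabLoose, tree, N = nrow(alignmentMatrix(a)),
                              rodaMode = rodaMode)
      treeBlock$distanceArea <- da
    }
    manifest$treatments[[tr]] <- list(
      composition = comp,
      heterogeneity = het,
      highEntropyRuns = list(count = nrow(runs),
                             largestLength = if (nrow(runs)) max(runs$length) else 0L,
                             runs = runs),
      otu = otuStats,
      saturation = if (!is.null(sat)) {
        list(crossoverDistance = sat$crossoverDistance,
             nPairs = nrow(sat$pairs),
             nUndefinedPairs = nrow(sat$undefinedPairs))
      },
      tree = treeBlock)
  }
  manifest
}

#' Serialise a pipeline manifest to JSON
#'
#' @param manifest output of [runPipeline()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
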