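#' Mark names of an object
#' @param x a chromapick object holding one or more marks.
#' @return character vector of mark identifiers.
#' @rdname markNames
#' @export
setMethod("markNames", "GenomeBins", function(x) x@markName)

#' @rdname markNames
#' @export
setMethod("markNames", "ProfileMatrix", function(x) x@markName)

#' @rdname markNames
#' @export
setMethod("markNames", "ProfileStack",
          function(x) vapply(x@profiles, function(p) p@markName, character(1)))

#' @rdname markNames
#' @export
setMethod("markNames", "AffinityMatrix", function(x) colnames(x@coefficients))

#' @rdname markNames
#' @export
setMethod("markNames", "MarkClustering", function(x) names(x@assignment))

#' @rdname markNames
#' @export
setMethod("markNames", "PatternModel", function(x) x@markNames)

#' Bin size of an object
#' @param x a `GenomeBins`, `ProfileMatrix` or `ProfileStack`.
#' @return bin width in bp.
#' @rdname binSize
#' @export
setMethod("binSize", "GenomeBins", function(x) x@binSize)

#' @rdname binSize
#' @export
setMethod("binSize", "ProfileMatrix", function(x) x@binSize)

#' @rdname binSize
#' @export
setMethod("binSize", "ProfileStack", function(x) x@profiles[[1]]@binSize)

#' @rdname nLoci
#' @export
setMethod("nLoci", "ProfileMatrix", function(x) nrow(x@signal))

#' @rdname nLoci
#' @export
setMethod("nLoci", "ProfileStack", function(x) nrow(x@profiles[[1]]@signal))

#' @rdname profileLength
#' @export
setMethod("profileLength", "ProfileMatrix", function(x) ncol(x@signal))

#' @rdname profileLength
#' @export
setMethod("profileLength", "ProfileStack", function(x) ncol(x@profiles[[1]]@signal))

#' @rdname profileLength
#' @export
setMethod("profileLength", "PatternModel", function(x) x@L)

#' @rdname affinityWeights
#' @export
setMethod("affinityWeights", "AffinityMatrix", function(x) {
  A <- x@coefficients
  (abs(A) + abs(t(A))) / 2
})

#' Extract a member ProfileMatrix from a stack
#' @param x a `ProfileStack`.
#' @param name mark name.
#' @return the `ProfileMatrix` for that mark.
#' @export
setMethod("$", "ProfileStack", function(x, name) {
  i <- match(name, markNames(x))
  if (is.na(i)) stop("no mark named '", name, "' in stack")
  x@profiles[[i]]
})

#' Loci of a profile container
#' @param x a `ProfileMatrix` or `ProfileStack`.
#' @return `GRanges` of the profiled windows.
#' @export
profileLoci <- function(x) {
  if (is(x, "ProfileStack")) x@profiles[[1]]@loci
  else if (is(x, "ProfileMatrix")) x@loci
  else stop("profileLoci() expects a ProfileMatrix or ProfileStack")
}

setMethod("show", "GenomeBins", function(object) {
  cat("GenomeBins:", object@markName, "\n")
  cat("  bin size:", object@binSize, "bp;",
      length(object@values), "chromosome(s);",
      sum(lengths(object@values)), "bins\n")
})

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", object@markName, "\n")
  cat(sprintf("  %d loci x %d bins (bin %d bp, flank %d bp)\n",
              nrow(object@signal), ncol(object@signal),
              object@binSize, object@flank))
})

setMethod("show", "ProfileStack", function(object) {
  cat(sprintf("ProfileStack: %d mark(s), %d loci x %d bins\n",
              length(object@profiles), nLoci(object), profileLength(object)))
  cat("  marks:", paste(markNames(object), collapse = ", "), "\n")
})

setMethod("show", "AffinityMatrix", function(object) {
  N <- ncol(object@coefficients)
  cat(sprintf("AffinityMatrix: %d marks, lambda = %g\n", N, object@lambda))
  nz <- sum(abs(object@coefficients) > 1e-8 * max(abs(object@coefficients), 1e-300))
  cat(sprintf("  %d / %d off-diagonal coefficients above tolerance\n", nz, N * (N - 1L)))
})

setMethod("show", "LambdaScan", function(object) {
  cat(sprintf("LambdaScan: %d candidate(s), chosen lambda = %g\n",
              nrow(object@table), object@chosen))
  print(head(object@table, 10))
})

setMethod("show", "MarkClustering", function(object) {
  cat(sprintf("MarkClustering: %d marks in %d cluster(s)\n",
              length(object@assignment), object@K))
  for (k in seq_len(object@K)) {
    members <- names(object@assignment)[object@assignment == k]
    rep_k <- object@representatives[as.character(k)]
    tag <- if (!is.na(rep_k)) paste0(" [rep: ", rep_k, "]") else ""
    cat(sprintf("  cluster %d%s: %s\n", k, tag, paste(members, collapse = ", ")))
  }
})

setMethod("show", "PatternModel", function(object) {
  K <- nrow(object@centroids)
  cat(sprintf("PatternModel: K = %d patterns over %d mark(s) x %d bins\n",
              K, length(object@markNames), object@L))
  sizes <- tabulate(object@labels, nbins = K)
  ord <- object@patternOrder
  cat("  sizes (CP order):", paste(sizes[ord], collapse = ", "), "\n")
})

setMethod("show", "ScanConfig", function(object) {
  cat(sprintf("ScanConfig: window %d bp, step %d bp, threshold %.2f, strands %s\n",
              object@window, object@step, object@threshold, object@strands))
  cat("  patterns:", paste(object@patterns, collapse = ", "), "\n")
})

#' Construct a scan configuration
#'
#' @param window window size in bp; must span exactly the pattern length.
#' @param step sliding step in bp.
#' @param threshold per-mark Pearson correlation cutoff in `(-1, 1)`.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param patterns integer centroid ids to match. Defaults to the active
#'   patterns CP1-CP4 resolved against the model at scan time (`NULL`).
#' @return a [ScanConfig-class] object.
#' @export
scanConfig <- function(window = 10000L, step = 2000L, threshold = 0.75,
                       strands = "both", patterns = NULL) {
  new("ScanConfig",
      window = as.integer(window), step = as.integer(step),
      threshold = as.numeric(threshold), strands = strands,
      patterns = as.integer(patterns %||% integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
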