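#' @rdname markNames
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))

#' @rdname binSize
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Number of loci (rows) in a profile container
#' @param x a `ProfileMatrix` or `ProfileStack`.
#' @return integer count of loci.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Bins per locus in a profile container
#' @param x a `ProfileMatrix`, `ProfileStack` or `PatternModel`.
#' @return integer number of bins per locus (per mark block).
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' Symmetrized non-negative affinity weights
#'
#' Returns `W = (|A| + |A^T|)/2`: symmetric, non-negative, zero diagonal.
#' All clustering and cross-dataset comparison operate on `W`, matching the
#' unordered-pair view of mark-mark affinity.
#'
#' @param x an `AffinityMatrix`.
#' @return symmetric N x N numeric matrix.
#' @export
setGeneric("affinityWeights", function(x) standardGeneric("affinityWeights"))
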