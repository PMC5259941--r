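#' @import methods
#' @importFrom stats cor cutree hclust as.dist median sd runif rnorm rlnorm
#' @importFrom utils head count.fields
NULL

#' Binned genome-wide signal for one chromatin mark
#'
#' Holds a fixed-resolution binned signal track: one numeric vector per
#' chromosome, with `ceiling(chromLength / binSize)` bins each. Bin values
#' are non-negative summed signal (tag-count-like units).
#'
#' @slot markName single mark identifier (e.g. `"H3K4me3"`).
#' @slot binSize bin width in bp.
#' @slot values named list, one numeric vector of bin values per chromosome.
#' @slot seqlengths named numeric vector of chromosome lengths in bp.
#' @export
setClass("GenomeBins",
  representation(
    markName   = "character",
    binSize    = "integer",
    values     = "list",
    seqlengths = "numeric"
  )
)

setValidity("GenomeBins", function(object) {
  msg <- character()
  if (length(object@markName) != 1L) msg <- c(msg, "markName must be a single string")
  if (length(object@binSize) != 1L || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (!identical(sort(names(object@values)), sort(names(object@seqlengths))))
    msg <- c(msg, "values and seqlengths must name the same chromosomes")
  for (chrom in names(object@values)) {
    v <- object@values[[chrom]]
    nb <- as.integer(ceiling(object@seqlengths[[chrom]] / object@binSize))
    if (length(v) != nb)
      msg <- c(msg, sprintf("chromosome %s: expected %d bins, got %d", chrom, nb, length(v)))
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, sprintf("chromosome %s: bin values must be finite and >= 0", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' Promoter profile matrix for one chromatin mark
#'
#' An M loci x L bins matrix of signal extracted around transcription start
#' sites (or genomic windows). Rows on the minus strand are stored 5'-to-3'
#' relative to transcription (i.e. reversed at extraction time).
#'
#' @slot markName mark identifier.
#' @slot signal numeric matrix, M loci x L bins.
#' @slot loci [GenomicRanges::GRanges] of the extracted windows, one per row,
#'   carrying the source TSS `gene_id` in its metadata columns.
#' @slot binSize bin width in bp.
#' @slot flank half-window size in bp; `L = 2 * flank / binSize`.
#' @export
setClass("ProfileMatrix",
  representation(
    markName = "character",
    signal   = "matrix",
    loci     = "GRanges",
    binSize  = "integer",
    flank    = "integer"
  )
)

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  L <- as.integer(2L * object@flank / object@binSize)
  if (ncol(object@signal) != L)
    msg <- c(msg, sprintf("signal has %d columns; expected L = 2*flank/binSize = %d",
                          ncol(object@signal), L))
  if (nrow(object@signal) != length(object@loci))
    msg <- c(msg, "number of signal rows must equal number of loci")
  if (object@flank %% object@binSize != 0L)
    msg <- c(msg, "flank must be divisible by binSize")
  if (length(msg)) msg else TRUE
})

#' Stack of profile matrices over a shared locus index
#'
#' Ordered collection of N [ProfileMatrix] objects for N marks, all sharing
#' an identical locus index. Column-vectorizing each member (row-major over
#' loci) yields the per-mark profile vectors whose side-by-side arrangement
#' is the data matrix used for self-representation.
#'
#' @slot profiles list of [ProfileMatrix], one per mark, unique mark names.
#' @export
setClass("ProfileStack", representation(profiles = "list"))

setValidity("ProfileStack", function(object) {
  ps <- object@profiles
  if (!length(ps)) return("stack must contain at least one ProfileMatrix")
  if (!all(vapply(ps, is, logical(1), class2 = "ProfileMatrix")))
    return("all elements must be ProfileMatrix objects")
  nm <- vapply(ps, function(p) p@markName, character(1))
  if (anyDuplicated(nm)) return("mark names must be unique")
  dims <- vapply(ps, function(p) dim(p@signal), integer(2))
  if (length(ps) > 1L && (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L))
    return("all member matrices must share identical M and L")
  TRUE
})

#' Sparse self-representation affinity matrix over marks
#'
#' Column i holds the L1-penalized coefficients expressing mark i's
#' genome-wide promoter profile vector as a weighted sum of the other marks'
#' vectors; the diagonal is exactly zero. The symmetrized non-negative
#' weights `(|A| + |A^T|)/2` are available via [affinityWeights()].
#'
#' @slot coefficients N x N numeric matrix with mark-name dimnames.
#' @slot lambda the L1 penalty weight used for the solve.
#' @export
setClass("AffinityMatrix",
  representation(coefficients = "matrix", lambda = "numeric")
)

setValidity("AffinityMatrix", function(object) {
  A <- object@coefficients
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "coefficient matrix must be square")
  if (any(diag(A) != 0)) msg <- c(msg, "diagonal must be exactly zero")
  if (is.null(rownames(A)) || is.null(colnames(A)) || !identical(rownames(A), colnames(A)))
    msg <- c(msg, "matrix must carry identical row/column mark names")
  if (length(object@lambda) != 1L || isTRUE(object@lambda < 0))
    msg <- c(msg, "lambda must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Lambda-selection scan
#'
#' Records, for each candidate penalty weight, the cross-dataset concordance
#' (Pearson correlation of the symmetrized affinity upper triangles), the
#' sparsity of both solutions, and their total L1 norms; `chosen` is the
#' grid value with the highest concordance (ties broken toward the smallest
#' lambda).
#'
#' @slot table data.frame with columns `lambda`, `concordance`, `sparsity1`,
#'   `sparsity2`, `l1norm1`, `l1norm2`.
#' @slot chosen the selected lambda.
#' @export
setClass("LambdaScan", representation(table = "data.frame", chosen = "numeric"))

#' Hierarchical clustering of marks with representatives
#'
#' @slot assignment named integer vector mark -> cluster label in `1..K`.
#' @slot representatives named character vector, one mark per cluster
#'   (names are cluster labels); empty until [selectRepresentatives()].
#' @slot tree the `hclust` merge tree (list slot).
#' @slot K number of clusters.
#' @export
setClass("MarkClustering",
  representation(assignment = "integer", representatives = "character",
                 tree = "ANY", K = "integer")
)

setValidity("MarkClustering", function(object) {
  msg <- character()
  if (is.null(names(object@assignment))) msg <- c(msg, "assignment must be named by mark")
  if (!all(object@assignment %in% seq_len(object@K)))
    msg <- c(msg, "cluster labels must lie in 1..K")
  if (length(object@representatives)) {
    if (anyDuplicated(object@representatives))
      msg <- c(msg, "representatives must be pairwise distinct")
    if (!all(object@representatives %in% names(object@assignment)))
      msg <- c(msg, "representatives must be marks of the clustering")
  }
  if (length(msg)) msg else TRUE
})

#' K-means model of combinatorial promoter patterns
#'
#' Centroids live in the concatenated space of the representative marks:
#' each centroid is a length `N' * L` vector made of N' mark blocks of L
#' bins. `patternOrder` maps display rank (CP1, CP2, ...) to cluster id
#' once [rankByExpression()] has been applied; before ranking it is the
#' identity.
#'
#' @slot centroids K x (N'*L) numeric matrix.
#' @slot labels integer vector of per-locus cluster ids in `1..K`.
#' @slot markNames the N' representative marks, in block order.
#' @slot L bins per mark block.
#' @slot seed random seed used for fitting.
#' @slot patternOrder integer permutation of `1..K`; `patternOrder[r]` is the
#'   cluster id displayed as CP`r`.
#' @slot totWithinSS total point-to-centroid squared distance of the fit.
#' @export
setClass("PatternModel",
  representation(
    centroids    = "matrix",
    labels       = "integer",
    markNames    = "character",
    L            = "integer",
    seed         = "integer",
    patternOrder = "integer",
    totWithinSS  = "numeric"
  )
)

setValidity("PatternModel", function(object) {
  msg <- character()
  K <- nrow(object@centroids)
  if (ncol(object@centroids) != length(object@markNames) * object@L)
    msg <- c(msg, "centroid length must equal N' * L")
  if (!all(object@labels %in% seq_len(K)))
    msg <- c(msg, "labels must lie in 1..K")
  if (!identical(sort(object@patternOrder), seq_len(K)))
    msg <- c(msg, "patternOrder must be a permutation of 1..K")
  if (length(msg)) msg else TRUE
})

#' Genome-scan configuration
#'
#' @slot window scan window in bp (must equal the pattern span `L * binSize`).
#' @slot step sliding step in bp.
#' @slot threshold per-mark Pearson correlation cutoff; a window is accepted
#'   for a pattern only if every per-mark correlation reaches it.
#' @slot strands `"+"`, `"-"` or `"both"`.
#' @slot patterns integer ids of the centroids to match (typically the
#'   active-promoter patterns).
#' @export
setClass("ScanConfig",
  representation(window = "integer", step = "integer", threshold = "numeric",
                 strands = "character", patterns = "integer")
)

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@threshold <= -1 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (-1, 1)")
  if (!object@strands %in% c("+", "-", "both"))
    msg <- c(msg, "strands must be '+', '-' or 'both'")
  if (object@window < 1L || object@step < 1L)
    msg <- c(msg, "window and step must be positive")
  if (length(msg)) msg else TRUE
})
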