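# Hierarchical clustering of marks from the self-representation affinity,
# cluster-count choice by cross-dataset overlap, and one representative
# mark per cluster.

#' Hierarchically cluster marks from an affinity matrix
#'
#' Converts the symmetrized weights `W` to a distance `D = 1 - W/max(W)`
#' (zero self-distance), agglomerates with average linkage and cuts the
#' tree into `K` clusters.
#'
#' @param A an [AffinityMatrix-class] object.
#' @param K number of clusters, `2 <= K <= N`.
#' @return a [MarkClustering-class] object (no representatives yet).
#' @export
clusterMarks <- function(A, K) {
  W <- affinityWeights(A)
  N <- ncol(W)
  K <- as.integer(K)
  if (K < 2L || K > N) stop("K must lie in [2, N]")
  mx <- max(W)
  if (mx == 0) stop("affinity matrix is all zero: no structure to cluster")
  D <- 1 - W / mx
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  assignment <- stats::cutree(tree, k = K)
  new("MarkClustering", assignment = assignment,
      representatives = character(), tree = tree, K = K)
}

#' Agreement between two mark clusterings
#'
#' Adjusted Rand index between the two assignments: 1 iff the partitions
#' are identical (up to label permutation), ~0 for independent partitions.
#'
#' @param c1,c2 [MarkClustering-class] objects over the same mark set.
#' @return ARI in `[-1, 1]`.
#' @export
clusterOverlap <- function(c1, c2) {
  if (!setequal(markNames(c1), markNames(c2)))
    stop("clusterings must cover the same mark set")
  marks <- markNames(c1)
  mclust::adjustedRandIndex(c1@assignment[marks], c2@assignment[marks])
}

#' Choose the mark-cluster count by cross-dataset overlap
#'
#' Clusters both affinity matrices at each candidate `K` and scores the
#' agreement of the resulting partitions; the `K` with the highest overlap
#' wins, ties going to the smallest `K`.
#'
#' @param A1,A2 [AffinityMatrix-class] objects over the same marks.
#' @param kGrid integer candidates within `[2, N]`.
#' @return list with `bestK` and `table` (data.frame of `K`, `overlap`).
#' @export
chooseKMarks <- function(A1, A2, kGrid) {
  overlap <- vapply(kGrid, function(k) {
    clusterOverlap(clusterMarks(A1, k), clusterMarks(A2, k))
  }, numeric(1))
  tab <- data.frame(K = as.integer(kGrid), overlap = overlap)
  bestK <- min(tab$K[tab$overlap == max(tab$overlap)])
  list(bestK = bestK, table = tab)
}

#' Pick one representative mark per cluster
#'
#' Default rule: the within-cluster affinity medoid — the member maximizing
#' the sum of symmetrized weights to the other members of its cluster
#' (singletons represent themselves; ties go to the lexicographically first
#' mark name). An explicit `override` replaces the rule, e.g. to use a
#' curated subset such as H3K4me2/H3K27ac/H2A.Z/H3K79me2.
#'
#' @param A the [AffinityMatrix-class] the clustering was built from.
#' @param clustering a [MarkClustering-class] over `A`'s marks.
#' @param override optional character vector of marks, one per cluster (in
#'   any order); each must belong to a distinct cluster.
#' @return the clustering with its `representatives` slot filled (named by
#'   cluster label).
#' @export
selectRepresentatives <- function(A, clustering, override = NULL) {
  W <- affinityWeights(A)
  marks <- markNames(clustering)
  assign <- clustering@assignment
  K <- clustering@K
  reps <- character(K)
  if (!is.null(override)) {
    if (length(override) != K)
      stop("override must name exactly one mark per cluster (", K, ")")
    bad <- setdiff(override, marks)
    if (length(bad)) stop("unknown mark(s) in override: ", paste(bad, collapse = ", "))
    cl <- assign[override]
    if (anyDuplicated(cl))
      stop("override marks must come from distinct clusters")
    reps[cl] <- override
  } else {
    for (k in seq_len(K)) {
      members <- marks[assign == k]
      if (length(members) == 1L) { reps[k] <- members; next }
      within <- vapply(members, function(m)
        sum(W[m, setdiff(members, m)]), numeric(1))
      best <- members[within == max(within)]
      reps[k] <- sort(best)[1]
    }
  }
  names(reps) <- as.character(seq_len(K))
  methods::initialize(clustering, representatives = reps)
}

#' Representative marks in cluster-label order
#' @param clustering a [MarkClustering-class] with representatives set.
#' @return character vector of representative mark names.
#' @export
representatives <- function(clustering) {
  if (!length(clustering@representatives))
    stop("no representatives selected yet; run selectRepresentatives()")
  unname(clustering@representatives)
}

#' Serialize a mark clustering to JSON
#' @param clustering a [MarkClustering-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClustering <- function(clustering, path) {
  obj <- list(
    K = clustering@K,
    assignment = as.list(clustering@assignment),
    representatives = as.list(clustering@representatives),
    merge_heights = if (!is.null(clustering@tree)) clustering@tree$height else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
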