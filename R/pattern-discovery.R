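# Recurrent combinatorial promoter patterns: K-means over concatenated
# representative-mark profiles, the modified Pearson similarity between
# patterns, expression-based ranking, and per-cluster profile aggregation.

#' Concatenate representative-mark profiles per locus
#'
#' For each locus, the L-bin profiles of the selected marks are joined into
#' one vector of length `N' * L`, blocks in the given order.
#'
#' @param stack a [ProfileStack-class] object.
#' @param representatives marks to concatenate, in block order.
#' @return M x (N'*L) numeric matrix; block boundaries recorded in the
#'   `"markNames"` and `"L"` attributes.
#' @export
concatenateProfiles <- function(stack, representatives) {
  missing <- setdiff(representatives, markNames(stack))
  if (length(missing))
    stop("unknown representative(s): ", paste(missing, collapse = ", "))
  idx <- match(representatives, markNames(stack))
  X <- do.call(cbind, lapply(idx, function(i) stack@profiles[[i]]@signal))
  attr(X, "markNames") <- representatives
  attr(X, "L") <- profileLength(stack)
  X
}

# squared Euclidean distances from each row of X to each row of C
.distToCentroids <- function(X, C, xss = rowSums(X^2)) {
  d <- xss - 2 * X %*% t(C)
  sweep(d, 2, rowSums(C^2), "+")
}

# One Lloyd run from given initial centroids. The total point-to-centroid
# distance is asserted non-increasing across iterations (small numerical
# slack); empty clusters are re-seeded at the point farthest from its
# centroid.
.lloyd <- function(X, centroids, maxit = 100L) {
  xss <- rowSums(X^2)
  K <- nrow(centroids)
  labels <- integer(nrow(X))
  prev_tot <- Inf
  reseeds <- 0L
  for (it in seq_len(maxit)) {
    d <- .distToCentroids(X, centroids, xss)
    new_labels <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(nrow(X)), new_labels)]
    empty <- setdiff(seq_len(K), unique(new_labels))
    for (k in empty) {
      far <- which.max(dmin)
      centroids[k, ] <- X[far, ]
      new_labels[far] <- k
      dmin[far] <- 0
      reseeds <- reseeds + 1L
    }
    tot <- sum(pmax(dmin, 0))
    if (!length(empty)) {
      stopifnot(tot <= prev_tot + 1e-8 * (1 + abs(prev_tot)))
      prev_tot <- tot
    } else prev_tot <- tot   # reseeding redefines the objective
    if (identical(new_labels, labels) && it > 1L) break
    labels <- new_labels
    for (k in seq_len(K))
      centroids[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  d <- .distToCentroids(X, centroids, xss)
  tot <- sum(pmax(d[cbind(seq_len(nrow(X)), labels)], 0))
  list(labels = labels, centroids = centroids, tot = tot, reseeds = reseeds)
}

# k-means++ seeding: first centroid uniform, then rows drawn with
# probability proportional to squared distance from the nearest chosen
# centroid. Returns row indices.
.ppInit <- function(X, K, xss = rowSums(X^2)) {
  M <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(M, 1L)
  dist_to <- function(i) pmax(xss - 2 * as.numeric(X %*% X[i, ]) + xss[i], 0)
  d2 <- dist_to(idx[1])
  for (k in seq_len(K - 1L) + 1L) {
    tot <- sum(d2)
    idx[k] <- if (tot <= 0) sample.int(M, 1L)
              else sample.int(M, 1L, prob = d2 / tot)
    d2 <- pmin(d2, dist_to(idx[k]))
  }
  idx
}

#' Fit combinatorial promoter patterns by K-means
#'
#' Lloyd's algorithm with squared Euclidean distance, best of `restarts`
#' k-means++ seeded initializations (initial centroids are data rows) by
#' total point-to-centroid distance. Deterministic given `seed`.
#'
#' @param X concatenated profile matrix from [concatenateProfiles()] (or
#'   any numeric matrix; mark structure then defaults to one block).
#' @param K number of patterns, `2 <= K <= M`.
#' @param seed integer random seed, recorded in the model.
#' @param restarts number of initializations (default 10).
#' @param maxit Lloyd iteration cap per restart.
#' @return a [PatternModel-class] object.
#' @export
fitPatterns <- function(X, K, seed = 1L, restarts = 10L, maxit = 100L) {
  K <- as.integer(K)
  if (K < 1L || K > nrow(X)) stop("K must lie in [1, M]")
  marks <- attr(X, "markNames") %||% "signal"
  L <- attr(X, "L") %||% ncol(X)
  Xm <- unclass(X); attributes(Xm)[c("markNames", "L")] <- NULL
  best <- NULL
  old_seed <- .saveSeed()
  on.exit(.restoreSeed(old_seed))
  set.seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    init <- .ppInit(Xm, K)
    fit <- .lloyd(Xm, Xm[init, , drop = FALSE], maxit = maxit)
    if (is.null(best) || fit$tot < best$tot) best <- fit
  }
  if (best$reseeds > 0L)
    message(best$reseeds, " empty cluster(s) re-seeded at the farthest point")
  new("PatternModel", centroids = best$centroids,
      labels = as.integer(best$labels), markNames = marks, L = as.integer(L),
      seed = as.integer(seed), patternOrder = seq_len(K),
      totWithinSS = best$tot)
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreSeed <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Cluster-count diagnostics for pattern discovery
#'
#' For each candidate `K`, fits patterns and records the total
#' point-to-centroid distance plus the mean silhouette width, computed on a
#' fixed-seed subsample of at most `cap` loci for tractability. No K is
#' chosen automatically: the curves are returned for the user to inspect.
#'
#' @param X concatenated profile matrix.
#' @param kGrid integer candidates in `[2, M-1]`.
#' @param seed random seed (subsample and K-means restarts).
#' @param cap silhouette subsample size (default 5000).
#' @param restarts K-means restarts per grid point.
#' @return data.frame with columns `K`, `silhouette`, `totWithinSS`. If all
#'   loci are identical the silhouette is undefined and returned as `NA`
#'   with a warning.
#' @export
diagnoseK <- function(X, kGrid, seed = 1L, cap = 5000L, restarts = 10L) {
  M <- nrow(X)
  kGrid <- as.integer(kGrid)
  if (any(kGrid < 2L | kGrid > M - 1L)) stop("kGrid must lie within [2, M-1]")
  old_seed <- .saveSeed()
  on.exit(.restoreSeed(old_seed))
  set.seed(as.integer(seed))
  sub <- if (M > cap) sort(sample(M, cap)) else seq_len(M)
  Xm <- unclass(X); attributes(Xm)[c("markNames", "L")] <- NULL
  degenerate <- all(apply(Xm[sub, , drop = FALSE], 2, function(col) length(unique(col)) == 1L))
  dsub <- if (!degenerate) stats::dist(Xm[sub, , drop = FALSE]) else NULL
  if (degenerate) warning("all subsampled loci identical; silhouette undefined")
  rows <- lapply(kGrid, function(k) {
    model <- fitPatterns(X, k, seed = seed, restarts = restarts)
    sil <- NA_real_
    lab <- model@labels[sub]
    if (!degenerate && length(unique(lab)) > 1L) {
      sw <- cluster::silhouette(lab, dsub)
      sil <- mean(sw[, "sil_width"])
    }
    data.frame(K = k, silhouette = sil, totWithinSS = model@totWithinSS)
  })
  do.call(rbind, rows)
}

#' Modified Pearson correlation between two concatenated patterns
#'
#' Splits both vectors into `nMarks` blocks of `L` bins and returns the
#' mean over blocks of the Pearson correlation of matching blocks. Blocks
#' in which either side has zero variance carry no shape information and
#' are excluded from the mean with a warning; the count of excluded blocks
#' is attached as attribute `"excluded"`.
#'
#' @param p,q numeric vectors of length `nMarks * L`.
#' @param nMarks number of mark blocks.
#' @param L bins per block.
#' @return similarity in `[-1, 1]` (`NaN` if every block is degenerate).
#' @export
modifiedPCC <- function(p, q, nMarks, L) {
  if (length(p) != nMarks * L || length(q) != nMarks * L)
    stop("vectors must have length nMarks * L")
  r <- numeric(nMarks)
  ok <- logical(nMarks)
  for (b in seq_len(nMarks)) {
    idx <- ((b - 1L) * L + 1L):(b * L)
    pb <- p[idx]; qb <- q[idx]
    if (stats::sd(pb) == 0 || stats::sd(qb) == 0) next
    r[b] <- stats::cor(pb, qb)
    ok[b] <- TRUE
  }
  if (!all(ok))
    warning(sum(!ok), " zero-variance block(s) excluded from modified PCC")
  out <- if (any(ok)) mean(r[ok]) else NaN
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Match patterns between two models by modified PCC
#'
#' Pairs centroids of the two models so that each is used at most once.
#' `method = "greedy"` (default) repeatedly takes the best remaining pair;
#' `method = "optimal"` enumerates assignments (available for
#' `min(K1, K2) <= 8`) and maximizes the total modified PCC.
#'
#' @param model1,model2 [PatternModel-class] objects with equal `N'` and `L`.
#' @param method `"greedy"` or `"optimal"`.
#' @return data.frame with columns `pattern1`, `pattern2`, `modifiedPCC`;
#'   unmatched centroid ids (on the larger side) in attribute
#'   `"unmatched"`.
#' @export
matchPatterns <- function(model1, model2, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (length(model1@markNames) != length(model2@markNames) || model1@L != model2@L)
    stop("models must share N' and L")
  K1 <- nrow(model1@centroids); K2 <- nrow(model2@centroids)
  S <- matrix(NA_real_, K1, K2)
  for (i in seq_len(K1)) for (j in seq_len(K2))
    S[i, j] <- suppressWarnings(as.numeric(
      modifiedPCC(model1@centroids[i, ], model2@centroids[j, ],
                  length(model1@markNames), model1@L)))
  n <- min(K1, K2)
  if (method == "optimal") {
    if (n > 8L) stop("optimal matching supported for min(K) <= 8")
    small_rows <- K1 <= K2
    kS <- if (small_rows) K1 else K2
    kL <- if (small_rows) K2 else K1
    best <- NULL; best_tot <- -Inf
    ii <- seq_len(kS)
    for (perm in .permutations(kL, kS)) {
      tot <- if (small_rows) sum(S[cbind(ii, perm)], na.rm = TRUE)
             else sum(S[cbind(perm, ii)], na.rm = TRUE)
      if (tot > best_tot) { best_tot <- tot; best <- perm }
    }
    pairs <- if (small_rows) cbind(seq_len(kS), best) else cbind(best, seq_len(kS))
  } else {
    Sw <- S
    pairs <- matrix(0L, n, 2)
    for (t in seq_len(n)) {
      ij <- which(Sw == max(Sw, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pairs[t, ] <- ij
      Sw[ij[1], ] <- -Inf; Sw[, ij[2]] <- -Inf
    }
  }
  out <- data.frame(pattern1 = as.integer(pairs[, 1]),
                    pattern2 = as.integer(pairs[, 2]),
                    modifiedPCC = S[pairs])
  out <- out[order(out$pattern1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- if (K1 > n) setdiff(seq_len(K1), out$pattern1)
                            else setdiff(seq_len(K2), out$pattern2)
  out
}

# all permutations of 1..n as an n! x n integer matrix
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- .permMatrix(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    vals <- setdiff(seq_len(n), i)
    cbind(i, matrix(vals[p], nrow(p)))
  })
  do.call(rbind, blocks)
}

# all injections of 1..k into 1..n (ordered k-tuples of distinct values)
.permutations <- function(n, k = n) {
  if (k == n) return(asplit(.permMatrix(n), 1))
  rec <- function(avail, k) {
    if (k == 0L) return(list(integer()))
    do.call(c, lapply(seq_along(avail), function(i)
      lapply(rec(avail[-i], k - 1L), function(r) c(avail[i], r))))
  }
  rec(seq_len(n), k)
}

#' Rank patterns by target-gene expression
#'
#' Orders clusters by descending median expression of their member genes
#' and records the order so cluster `patternOrder[1]` is displayed as CP1
#' (the most active pattern), etc. Ties are broken by mean expression, then
#' by original cluster id; clusters with no expression data rank last and
#' are flagged with a warning.
#'
#' @param model a [PatternModel-class] object.
#' @param expression named numeric vector (or two-column data.frame
#'   `gene_id`, `value`) of per-gene expression.
#' @param geneIds character vector mapping each locus (row of the fitted
#'   matrix, in label order) to its gene id.
#' @return the model with `patternOrder` set.
#' @export
rankByExpression <- function(model, expression, geneIds) {
  if (is.data.frame(expression))
    expression <- stats::setNames(expression[[2]], expression[[1]])
  if (length(geneIds) != length(model@labels))
    stop("geneIds must have one entry per locus")
  K <- nrow(model@centroids)
  vals <- expression[geneIds]
  med <- mn <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    v <- vals[model@labels == k]
    v <- v[!is.na(v)]
    if (length(v)) { med[k] <- stats::median(v); mn[k] <- mean(v) }
  }
  if (anyNA(med))
    warning("cluster(s) without expression data ranked last: ",
            paste(which(is.na(med)), collapse = ", "))
  ord <- order(-med, -mn, seq_len(K), na.last = TRUE)
  methods::initialize(model, patternOrder = as.integer(ord))
}

#' CP label (display rank) of each locus
#' @param model a ranked [PatternModel-class] object.
#' @return integer vector: locus i belongs to pattern CP`r` where `r` is
#'   the returned value.
#' @export
cpLabels <- function(model) {
  rank_of <- order(model@patternOrder)   # cluster id -> display rank
  rank_of[model@labels]
}

#' Per-cluster mean signal profiles
#'
#' Bin-wise mean profile of each cluster over an auxiliary track (e.g.
#' PolII) or any profile matrix sharing the model's locus index. Empty
#' clusters are omitted with a warning.
#'
#' @param labels integer per-locus cluster ids.
#' @param profiles a [ProfileMatrix-class] or plain matrix with one row per
#'   locus.
#' @return numeric matrix, one row per non-empty cluster (rownames are
#'   cluster ids).
#' @export
aggregateClusterSignal <- function(labels, profiles) {
  sig <- if (is(profiles, "ProfileMatrix")) profiles@signal else as.matrix(profiles)
  if (nrow(sig) != length(labels))
    stop("labels and profile rows must align")
  ids <- sort(unique(labels))
  all_ids <- seq_len(max(labels))
  empty <- setdiff(all_ids, ids)
  if (length(empty))
    warning("empty cluster(s) omitted: ", paste(empty, collapse = ", "))
  out <- t(vapply(ids, function(k)
    colMeans(sig[labels == k, , drop = FALSE]), numeric(ncol(sig))))
  rownames(out) <- ids
  out
}

#' Serialize a pattern model to JSON
#' @param model a [PatternModel-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePatternModel <- function(model, path) {
  obj <- list(K = nrow(model@centroids), markNames = model@markNames,
              L = model@L, seed = model@seed,
              patternOrder = model@patternOrder,
              totWithinSS = model@totWithinSS,
              centroids = unname(model@centroids),
              labels = model@labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pattern model from JSON
#' @param path file written by [writePatternModel()].
#' @return a [PatternModel-class] object.
#' @export
readPatternModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PatternModel",
      centroids = matrix(as.numeric(obj$centroids), nrow = nrow(obj$centroids)),
      labels = as.integer(obj$labels), markNames = obj$markNames,
      L = as.integer(obj$L), seed = as.integer(obj$seed),
      patternOrder = as.integer(obj$patternOrder),
      totWithinSS = as.numeric(obj$totWithinSS))
}
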