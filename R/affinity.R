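# Sparse self-representation over chromatin marks.
#
# Each mark's vectorized promoter profile h_i is expressed as a sparse
# weighted sum of the other marks' profiles by solving, per column,
#
#     min_a  1/2 || h_i - H a ||_2^2 + lambda ||a||_1,   a_i = 0,
#
# the noisy-data relaxation of the exact self-expression program
# min ||A||_1 s.t. H = H A, diag(A) = 0. With N marks the problem reduces
# to the N x N Gram matrix G = H^T H and b = H^T h_i, so solve cost is
# independent of genome size once G is formed.

# Cyclic coordinate descent for the Gram-form lasso:
#   min 1/2 a'Ga - b'a + lambda ||a||_1  over coordinates in `free`.
# Returns the coefficient vector; attr "kkt_gap" holds the final relative
# KKT violation.
.lassoGram <- function(G, b, lambda, free, tol = 1e-6, maxit = 10000L) {
  N <- length(b)
  a <- numeric(N)
  d <- diag(G)
  Ga <- numeric(N)             # running G %*% a
  scale <- max(abs(b), lambda, 1e-300)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in free) {
      if (d[j] <= 0) next
      cj <- b[j] - Ga[j] + d[j] * a[j]
      new <- sign(cj) * max(abs(cj) - lambda, 0) / d[j]
      if (new != a[j]) {
        Ga <- Ga + G[, j] * (new - a[j])
        delta <- max(delta, abs(new - a[j]) * sqrt(d[j]))
        a[j] <- new
      }
    }
    # KKT: |b - Ga|_j <= lambda for zero coords, == lambda*sign(a_j) otherwise
    g <- b - Ga
    gap <- max(0, abs(g[free]) - lambda,
               abs(g[free][a[free] != 0] - lambda * sign(a[free][a[free] != 0])))
    if (gap / scale <= tol) {
      attr(a, "kkt_gap") <- gap / scale
      return(a)
    }
  }
  stop(sprintf("coordinate descent did not converge: relative KKT gap %.3g after %d iterations",
               gap / scale, maxit))
}

#' Solve the sparse self-representation program over marks
#'
#' Expresses each mark's vectorized profile as an L1-penalized weighted sum
#' of the other marks' profiles. Column i of the result minimizes
#' `0.5*||h_i - H a||^2 + lambda*||a||_1` with `a_i = 0` fixed; the
#' diagonal of the returned matrix is exactly zero. Columns are solved
#' independently, so results do not depend on solve order.
#'
#' @param stack a [ProfileStack-class] with `N >= 2` marks, or the
#'   `(M*L) x N` data matrix itself (columns = vectorized mark profiles).
#' @param lambda L1 penalty weight (> 0), on the raw signal scale.
#' @param standardize if `TRUE`, columns are scaled to unit Euclidean norm
#'   before the solve and coefficients mapped back; `lambda` is then
#'   interpreted on the standardized scale. Default `FALSE` (raw scale).
#' @param tol relative KKT/duality tolerance (default `1e-6`).
#' @param maxit maximum coordinate-descent sweeps per column.
#' @return an [AffinityMatrix-class] object.
#' @details An all-zero column gets a zero coefficient vector with a
#'   warning. Non-convergence is an error reporting the KKT gap.
#' @export
solveSelfRepresentation <- function(stack, lambda, standardize = FALSE,
                                    tol = 1e-6, maxit = 10000L) {
  H <- if (is(stack, "ProfileStack")) stackMatrix(stack) else as.matrix(stack)
  N <- ncol(H)
  if (N < 2L) stop("need at least 2 marks")
  if (length(lambda) != 1L || lambda <= 0) stop("lambda must be a single value > 0")
  nm <- colnames(H)
  if (is.null(nm)) nm <- paste0("mark", seq_len(N))
  norms <- sqrt(colSums(H^2))
  zero <- norms == 0
  if (standardize) {
    Hs <- H
    Hs[, !zero] <- sweep(H[, !zero, drop = FALSE], 2, norms[!zero], "/")
    H <- Hs
  }
  G <- crossprod(H)
  A <- matrix(0, N, N, dimnames = list(nm, nm))
  for (i in seq_len(N)) {
    if (zero[i]) {
      warning("column '", nm[i], "' is all zero; coefficients set to 0")
      next
    }
    free <- setdiff(seq_len(N), i)
    A[, i] <- .lassoGram(G, G[, i], lambda, free, tol = tol, maxit = maxit)
    A[i, i] <- 0
  }
  if (standardize) {
    # map back to raw-scale coefficients: h_i ~ sum_j (n_i/n_j) a_ji h_j^raw
    for (i in which(!zero))
      A[!zero, i] <- A[!zero, i] * norms[i] / norms[!zero]
  }
  new("AffinityMatrix", coefficients = A, lambda = lambda)
}

#' Cross-dataset concordance of two affinity matrices
#'
#' Pearson correlation between the upper-triangular (i < j) entries of the
#' symmetrized weights `W = (|A|+|A^T|)/2` of the two matrices — for N
#' marks, the `N*(N-1)/2` unordered mark pairs.
#'
#' @param A1,A2 [AffinityMatrix-class] objects over the same marks, in the
#'   same order.
#' @return a single correlation value; `NaN` (with a warning) if either
#'   upper triangle has zero variance.
#' @export
compareAffinities <- function(A1, A2) {
  if (!identical(markNames(A1), markNames(A2)))
    stop("affinity matrices must share the same mark set and order")
  ut <- upper.tri(A1@coefficients)
  w1 <- affinityWeights(A1)[ut]
  w2 <- affinityWeights(A2)[ut]
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0) {
    warning("zero variance in affinity weights; concordance undefined")
    return(NaN)
  }
  stats::cor(w1, w2)
}

# Fraction of entries with |A| <= 1e-8 * max|A| (all-zero matrix counts as
# fully sparse), and total L1 norm.
.sparsity <- function(A) {
  a <- abs(A@coefficients)
  m <- max(a)
  if (m == 0) return(1)
  mean(a <= 1e-8 * m)
}

#' Select the penalty weight by cross-dataset concordance
#'
#' Solves the self-representation program on two datasets (e.g. two cell
#' lines) over a grid of penalty weights and picks the lambda whose two
#' affinity matrices agree best ([compareAffinities()]); ties go to the
#' smallest lambda. Sparsity and total L1 norm are recorded per grid point.
#'
#' @param stack1,stack2 [ProfileStack-class] objects sharing the mark set.
#' @param grid numeric vector of candidate lambdas (> 0).
#' @param ... passed to [solveSelfRepresentation()].
#' @return a [LambdaScan-class] object.
#' @export
selectLambda <- function(stack1, stack2, grid, ...) {
  if (!length(grid)) stop("empty lambda grid")
  if (!identical(markNames(stack1), markNames(stack2)))
    stop("stacks must share the same mark set and order")
  rows <- lapply(grid, function(lam) {
    A1 <- solveSelfRepresentation(stack1, lam, ...)
    A2 <- solveSelfRepresentation(stack2, lam, ...)
    data.frame(lambda = lam,
               concordance = suppressWarnings(compareAffinities(A1, A2)),
               sparsity1 = .sparsity(A1), sparsity2 = .sparsity(A2),
               l1norm1 = sum(abs(A1@coefficients)),
               l1norm2 = sum(abs(A2@coefficients)))
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$concordance)
  if (!any(ok)) stop("concordance undefined at every grid value")
  best <- max(tab$concordance[ok])
  chosen <- min(tab$lambda[ok][tab$concordance[ok] == best])
  new("LambdaScan", table = tab, chosen = chosen)
}

#' Write an affinity matrix as TSV
#' @param A an [AffinityMatrix-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAffinity <- function(A, path) {
  utils::write.table(A@coefficients, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read an affinity matrix from TSV
#' @param path TSV written by [writeAffinity()].
#' @param lambda the penalty recorded with the matrix (default `NA`).
#' @return an [AffinityMatrix-class] object.
#' @export
readAffinity <- function(path, lambda = NA_real_) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  new("AffinityMatrix", coefficients = m, lambda = as.numeric(lambda))
}
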