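# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, direct formulas, double loops) and never call the code
# paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# default penalty used on the synthetic fixture's raw signal scale
FIXTURE_LAMBDA <- 50

# ---- tiny GenomeBins builders -------------------------------------------

toyBins <- function(values, markName = "toy", binSize = 100L,
                    chrom = "chr1") {
  if (!is.list(values)) values <- setNames(list(values), chrom)
  sizes <- vapply(values, function(v) length(v) * binSize, numeric(1))
  genomeBins(markName, values, sizes, binSize)
}

writeTempBedGraph <- function(lines) {
  path <- tempfile(fileext = ".bedGraph")
  writeLines(lines, path)
  path
}

writeTempBed6 <- function(df) {
  path <- tempfile(fileext = ".bed")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# ---- exact lasso oracle by sign-pattern enumeration ----------------------

# Solves min 1/2||y - X a||^2 + lambda ||a||_1 with a restricted to the
# `free` coordinates by enumerating all sign patterns on `free`, solving
# the stationarity system per pattern and checking the KKT conditions.
lassoOracle <- function(X, y, lambda, free = seq_len(ncol(X)), tol = 1e-9) {
  p <- ncol(X)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), length(free))))
  for (r in seq_len(nrow(signs))) {
    s <- numeric(p); s[free] <- signs[r, ]
    act <- which(s != 0)
    a <- numeric(p)
    if (length(act)) {
      XA <- X[, act, drop = FALSE]
      rhs <- crossprod(XA, y) - lambda * s[act]
      sol <- tryCatch(solve(crossprod(XA), rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) * s[act] < 0) || any(abs(sol) < tol & s[act] != 0)) next
      a[act] <- sol
    }
    grad <- crossprod(X, y - X %*% a)
    inact <- setdiff(free, act)
    if (all(abs(grad[inact]) <= lambda + 1e-7)) return(a)
  }
  stop("no sign pattern satisfied the KKT conditions")
}

# ---- direct-formula oracles ---------------------------------------------

# adjusted Rand index from the contingency table, by hand
ariOracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# modified PCC by direct per-block cor() calls
modifiedPCCOracle <- function(p, q, nMarks, L) {
  rs <- vapply(seq_len(nMarks), function(b) {
    idx <- ((b - 1) * L + 1):(b * L)
    suppressWarnings(cor(p[idx], q[idx]))
  }, numeric(1))
  mean(rs[!is.na(rs)])
}

# ---- naive reference genome scan ----------------------------------------

# Double-loop scan: every window x strand x centroid fully enumerated with
# cor(); conjunctive per-mark threshold; best centroid by mean PCC.
naiveScan <- function(binsList, model, window = 10000L, step = 2000L,
                      threshold = 0.75, patterns = NULL) {
  marks <- markNames(model)
  bs <- binSize(binsList[[1]])
  wb <- window %/% bs; sb <- step %/% bs
  L <- profileLength(model)
  pats <- patterns
  if (is.null(pats)) pats <- model@patternOrder[seq_len(min(4, nrow(model@centroids)))]
  rows <- list()
  for (chrom in names(binsList[[1]]@values)) {
    v <- lapply(marks, function(m) binsList[[m]]@values[[chrom]])
    nb <- length(v[[1]])
    for (w0 in seq(0, nb - wb, by = sb)) {
      for (st in c("+", "-")) {
        best <- NULL
        flat <- any(vapply(v, function(x) sd(x[(w0 + 1):(w0 + wb)]) == 0, logical(1)))
        if (flat) next
        for (p in pats) {
          pcc <- vapply(seq_along(marks), function(b) {
            x <- v[[b]][(w0 + 1):(w0 + wb)]
            if (st == "-") x <- rev(x)
            cb <- model@centroids[p, ((b - 1) * L + 1):(b * L)]
            if (sd(cb) == 0) return(-Inf)
            cor(x, cb)
          }, numeric(1))
          if (all(pcc >= threshold)) {
            if (is.null(best) || mean(pcc) > best$meanPCC)
              best <- list(pattern = p, meanPCC = mean(pcc), minPCC = min(pcc))
          }
        }
        if (!is.null(best))
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start0 = w0 * bs, strand = st,
            pattern = best$pattern, minPCC = best$minPCC,
            meanPCC = best$meanPCC)
      }
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(), start0 = integer(),
                                       strand = character(), pattern = integer(),
                                       minPCC = numeric(), meanPCC = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start0, out$strand), ]
}

# hits GRanges -> comparable data.frame
hitsToFrame <- function(hits) {
  df <- data.frame(chrom = as.character(seqnames(hits)),
                   start0 = start(hits) - 1L,
                   strand = as.character(strand(hits)),
                   pattern = S4Vectors::mcols(hits)$pattern,
                   minPCC = S4Vectors::mcols(hits)$minPCC,
                   meanPCC = S4Vectors::mcols(hits)$meanPCC)
  df <- df[order(df$chrom, df$start0, df$strand), ]
  rownames(df) <- NULL
  df
}

# small two-dataset profile-stack fixture
twinStacks <- function(seed = 1L, nPromotersPerClass = 50L) {
  cfg <- synthConfig(nPromotersPerClass = nPromotersPerClass)
  list(s1 = simulateStack(cfg, seed = seed),
       s2 = simulateStack(cfg, seed = seed + 1000L))
}
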