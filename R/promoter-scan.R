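# Sliding-window scan of binned mark tracks for loci whose per-mark
# profiles all correlate with an active-promoter pattern.

# Per-mark Pearson correlations of every window against one centroid
# block: X is wb x nwin (one window per column), cblock length wb.
.windowCor <- function(X, cblock) {
  suppressWarnings(as.numeric(stats::cor(X, cblock)))
}

#' Scan binned tracks for promoter-patterned windows
#'
#' Slides a window of `config@window` bp with step `config@step` along every
#' chromosome and, for each requested strand, correlates the per-mark
#' window profiles against each active pattern centroid (minus-strand
#' candidates are the reversed windows). A (window, strand, centroid)
#' triple passes only if *every* per-mark Pearson correlation reaches the
#' threshold; each passing window is reported once with its best centroid
#' by mean per-mark correlation (the modified PCC). Windows where any mark
#' has zero variance are skipped and counted.
#'
#' @param binsList named list of [GenomeBins-class], one per representative
#'   mark; must cover the model's marks.
#' @param model a [PatternModel-class]; block order defines the mark order.
#' @param config a [ScanConfig-class]. An empty `patterns` slot defaults to
#'   the active patterns: the top `min(4, K)` clusters in CP order.
#' @return `GRanges` of hits with metadata columns `pattern` (centroid id),
#'   one `pcc_<mark>` column per mark, `minPCC` and `meanPCC`; the number
#'   of zero-variance windows skipped is in `metadata(hits)$skipped`.
#' @export
scanGenome <- function(binsList, model, config = scanConfig()) {
  marks <- model@markNames
  missing <- setdiff(marks, names(binsList))
  if (length(missing)) stop("missing tracks for mark(s): ", paste(missing, collapse = ", "))
  binsList <- binsList[marks]
  bs <- binsList[[1]]@binSize
  if (config@window %% bs != 0L || config@step %% bs != 0L)
    stop("window and step must be multiples of the bin size")
  wb <- config@window %/% bs
  if (wb != model@L)
    stop(sprintf("window spans %d bins but model patterns have L = %d", wb, model@L))
  sb <- config@step %/% bs
  pats <- if (length(config@patterns)) config@patterns
          else model@patternOrder[seq_len(min(4L, nrow(model@centroids)))]
  strands <- if (config@strands == "both") c("+", "-") else config@strands
  Np <- length(marks)
  centroid_blocks <- lapply(pats, function(p)
    lapply(seq_len(Np), function(b)
      model@centroids[p, ((b - 1L) * model@L + 1L):(b * model@L)]))
  skipped <- 0L
  out <- list()
  for (chrom in names(binsList[[1]]@values)) {
    nb <- length(binsList[[1]]@values[[chrom]])
    if (nb < wb) next
    starts_bin <- seq.int(0L, nb - wb, by = sb)
    nwin <- length(starts_bin)
    idx <- outer(seq_len(wb), starts_bin, `+`)    # wb x nwin bin indices
    Xs <- lapply(marks, function(m) matrix(binsList[[m]]@values[[chrom]][idx], nrow = wb))
    flat <- Reduce(`|`, lapply(Xs, function(X)
      matrixStatsColSds(X) == 0))
    skipped <- skipped + sum(flat) * length(strands)
    for (st in strands) {
      # PCC(rev(x), c) == PCC(x, rev(c)): minus strand uses reversed blocks
      R <- array(NA_real_, dim = c(nwin, Np, length(pats)))
      for (p in seq_along(pats)) for (b in seq_len(Np)) {
        cb <- centroid_blocks[[p]][[b]]
        if (st == "-") cb <- rev(cb)
        if (stats::sd(cb) == 0) { R[, b, p] <- -Inf; next }
        R[, b, p] <- .windowCor(Xs[[b]], cb)
      }
      minP <- meanP <- matrix(NA_real_, nwin, length(pats))
      for (p in seq_along(pats)) {
        slices <- lapply(seq_len(Np), function(b) R[, b, p])
        minP[, p] <- do.call(pmin, slices)
        meanP[, p] <- Reduce(`+`, slices) / Np
      }
      masked <- ifelse(minP >= config@threshold, meanP, -Inf)
      if (is.null(dim(masked))) dim(masked) <- c(nwin, length(pats))
      bestp <- max.col(masked, ties.method = "first")
      pass <- which(!flat & is.finite(masked[cbind(seq_len(nwin), bestp)]))
      if (!length(pass)) next
      bp <- bestp[pass]
      gr <- GRanges(chrom,
                    IRanges(start = starts_bin[pass] * bs + 1L,
                            width = config@window),
                    strand = st)
      df <- S4Vectors::DataFrame(pattern = pats[bp],
                                 minPCC = minP[cbind(pass, bp)],
                                 meanPCC = meanP[cbind(pass, bp)])
      for (b in seq_len(Np))
        df[[paste0("pcc_", marks[b])]] <- R[cbind(pass, b, bp)]
      mcols(gr) <- df
      out[[length(out) + 1L]] <- gr
    }
  }
  hits <- if (length(out)) suppressWarnings(do.call(c, out)) else {
    g <- GRanges()
    mcols(g) <- S4Vectors::DataFrame(pattern = integer(), minPCC = numeric(),
                                     meanPCC = numeric())
    g
  }
  hits <- sort(hits, ignore.strand = TRUE)
  S4Vectors::metadata(hits)$skipped <- skipped
  hits
}

# column standard-deviation indicator helper (sd == 0 detection without
# forming full sd): returns per-column SDs
matrixStatsColSds <- function(X) {
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0))
}

#' Merge overlapping scan hits
#'
#' Default policy: overlapping same-strand hits matched to the same pattern
#' collapse to the single window with the best mean PCC. `mode = "none"`
#' returns the hits unchanged.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param mode `"best"` (default) or `"none"`.
#' @return `GRanges` of merged hits.
#' @export
mergeHits <- function(hits, mode = c("best", "none")) {
  mode <- match.arg(mode)
  if (mode == "none" || !length(hits)) return(hits)
  key <- paste(as.character(strand(hits)), mcols(hits)$pattern)
  kept <- lapply(split(seq_along(hits), key), function(ix) {
    sub <- hits[ix]
    red <- GenomicRanges::reduce(sub, with.revmap = TRUE, min.gapwidth = 0L,
                                 ignore.strand = FALSE)
    vapply(S4Vectors::mcols(red)$revmap, function(members)
      ix[members[which.max(mcols(sub)$meanPCC[members])]], integer(1))
  })
  out <- hits[sort(unlist(kept, use.names = FALSE))]
  S4Vectors::metadata(out) <- S4Vectors::metadata(hits)
  out
}

#' Classify scan hits against an annotation
#'
#' A hit overlapping any annotated TSS (extended by `flank` on both sides)
#' is `overlaps_annotation`; otherwise a hit falling within a gene body is
#' `unannotated_within_gene`; the rest are `unannotated_between_genes`.
#'
#' @param hits `GRanges` of (merged) scan hits.
#' @param tss `GRanges` of annotated TSS positions (width 1).
#' @param genes `GRanges` of gene-body intervals.
#' @param flank TSS flank in bp (default 5000, the promoter half-window).
#' @return the hits with an `annotation` metadata column plus a
#'   pattern-by-class count table in attribute-free form: list with
#'   elements `hits` and `summary`.
#' @export
classifyHits <- function(hits, tss, genes, flank = 5000L) {
  if (!length(tss) && !length(genes))
    warning("empty annotation: all hits classified as unannotated_between_genes")
  cls <- rep("unannotated_between_genes", length(hits))
  if (length(genes)) {
    within_gene <- IRanges::overlapsAny(hits, genes, ignore.strand = TRUE)
    cls[within_gene] <- "unannotated_within_gene"
  }
  if (length(tss)) {
    prom <- suppressWarnings(GenomicRanges::resize(tss, width = 2L * flank,
                                                   fix = "center", ignore.strand = TRUE))
    near_tss <- IRanges::overlapsAny(hits, prom, ignore.strand = TRUE)
    cls[near_tss] <- "overlaps_annotation"
  }
  mcols(hits)$annotation <- cls
  pat <- mcols(hits)$pattern
  lvls <- c("overlaps_annotation", "unannotated_between_genes", "unannotated_within_gene")
  summary <- as.data.frame.matrix(table(pattern = pat, class = factor(cls, levels = lvls)))
  list(hits = hits, summary = summary)
}

#' Write scan hits as BED6+ with per-mark PCC columns
#'
#' Columns: chrom, start, end, name (`CP<pattern>`), score
#' (`round(1000 * meanPCC)`), strand, then one per-mark PCC column and the
#' annotation class when present.
#'
#' @param hits `GRanges` of hits.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsBed <- function(hits, path) {
  md <- as.data.frame(mcols(hits))
  pcc_cols <- grep("^pcc_", names(md), value = TRUE)
  df <- data.frame(chrom = as.character(seqnames(hits)),
                   start = start(hits) - 1L, end = end(hits),
                   name = paste0("CP", md$pattern),
                   score = round(1000 * md$meanPCC),
                   strand = as.character(strand(hits)))
  for (cc in pcc_cols) df[[cc]] <- md[[cc]]
  if (!is.null(md$annotation)) df$annotation <- md$annotation
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
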