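#' @importFrom GenomicRanges GRanges coverage seqnames start end strand
#'   findOverlaps reduce width
#' @importFrom IRanges IRanges Views viewSums ranges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits runValue
#' @importFrom GenomeInfoDb seqlengths seqlevels keepSeqlevels
#' @importFrom rtracklayer import export
NULL

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' Construct a GenomeBins object from bin vectors
#'
#' @param markName mark identifier.
#' @param values named list of per-chromosome numeric bin vectors.
#' @param chromSizes named vector of chromosome lengths in bp.
#' @param binSize bin width in bp.
#' @return a [GenomeBins-class] object.
#' @export
genomeBins <- function(markName, values, chromSizes, binSize = 100L) {
  new("GenomeBins", markName = markName, binSize = as.integer(binSize),
      values = values, seqlengths = chromSizes[names(values)])
}

# Light structural pre-check so malformed data lines are reported with their
# line number before handing the file to the parser.
.checkBedGraphLines <- function(path) {
  fields <- utils::count.fields(path, sep = "", comment.char = "", blank.lines.skip = FALSE)
  if (!length(fields)) return(invisible(NULL))
  first <- vapply(strsplit(readLines(path, warn = FALSE), "[ \t]"), `[`, character(1), 1)
  skip <- is.na(fields) | first %in% c("track", "browser") | startsWith(first, "#") | first == ""
  bad <- which(!skip & fields != 4L)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in %s: expected 4 fields, found %d",
                 bad[1], path, fields[bad[1]]))
  invisible(NULL)
}

#' Read and bin a signal track
#'
#' Reads a bedGraph (or bigWig) track and sums signal into fixed-width bins:
#' each bin receives `sum(interval value x overlapping bp) / binSize`, so an
#' interval contributes to a bin in proportion to its overlap and total
#' binned mass equals `sum(value x interval length) / binSize`. Bins with no
#' data are 0.
#'
#' @param path bedGraph (`.bedGraph`/`.bg`) or bigWig (`.bw`/`.bigWig`) file.
#' @param chromSizes named vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 100).
#' @param markName mark identifier; defaults to the file base name.
#' @param scaleFactor optional multiplier applied to every bin (e.g. a
#'   per-million normalizer); default `NULL`, signal used as-is.
#' @return a [GenomeBins-class] object.
#' @details Intervals on chromosomes absent from `chromSizes` are skipped
#'   with a warning; intervals extending past a chromosome end are an error.
#' @export
readSignalTrack <- function(path, chromSizes, binSize = 100L, markName = NULL,
                            scaleFactor = NULL) {
  binSize <- as.integer(binSize)
  if (is.null(markName))
    markName <- sub("\\.(bedgraph|bg|bw|bigwig)$", "", basename(path), ignore.case = TRUE)
  is_bw <- grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)
  if (!is_bw) .checkBedGraphLines(path)
  gr <- if (is_bw) rtracklayer::import(path, format = "BigWig")
        else rtracklayer::import(path, format = "bedGraph")
  known <- as.character(seqnames(gr)) %in% names(chromSizes)
  if (!all(known)) {
    skipped <- unique(as.character(seqnames(gr))[!known])
    warning("skipping intervals on unknown chromosome(s): ",
            paste(skipped, collapse = ", "))
    gr <- gr[known]
  }
  oob <- end(gr) > chromSizes[as.character(seqnames(gr))]
  if (any(oob))
    stop("interval beyond chromosome bounds at ",
         as.character(seqnames(gr))[which(oob)[1]], ":", start(gr)[which(oob)[1]])
  vals <- lapply(names(chromSizes), function(chrom) {
    nb <- as.integer(ceiling(chromSizes[[chrom]] / binSize))
    sub <- gr[seqnames(gr) == chrom]
    if (!length(sub)) return(numeric(nb))
    cov <- coverage(ranges(sub), weight = S4Vectors::mcols(sub)$score,
                    width = nb * binSize)
    starts <- seq.int(1L, by = binSize, length.out = nb)
    v <- as.numeric(viewSums(Views(cov, start = starts, width = binSize))) / binSize
    pmax(v, 0)   # guard against float round-off in the Rle sums
  })
  names(vals) <- names(chromSizes)
  if (!is.null(scaleFactor))
    vals <- lapply(vals, `*`, as.numeric(scaleFactor))
  genomeBins(markName, vals, chromSizes, binSize)
}

#' Write binned signal back to bedGraph
#'
#' Emits one line per bin with a non-zero value (runs are not merged), using
#' 0-based half-open coordinates; the final bin of a chromosome is clipped
#' to the chromosome end.
#'
#' @param bins a [GenomeBins-class] object.
#' @param path output file path.
#' @param keepZero also emit zero-valued bins (default `FALSE`).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(bins, path, keepZero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(bins@values)) {
    v <- bins@values[[chrom]]
    idx <- if (keepZero) seq_along(v) else which(v != 0)
    if (!length(idx)) next
    starts <- (idx - 1L) * bins@binSize
    ends <- pmin(idx * bins@binSize, bins@seqlengths[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts, ends,
                       formatC(v[idx], digits = 10, format = "g")), con)
  }
  invisible(path)
}

#' Read a BED6 TSS file
#'
#' Each record is a single-bp TSS: `chromStart` is the 0-based TSS position,
#' `name` the gene id, `strand` `+` or `-`.
#'
#' @param path BED6 file.
#' @return `GRanges` of width-1 TSS positions with a `gene_id` column.
#' @export
readTSS <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("TSS strand must be '+' or '-' for every record")
  mcols(gr)$gene_id <- mcols(gr)$name
  gr
}

#' Extract strand-aware promoter profiles for one mark
#'
#' For each TSS the window `[position - flank, position + flank)` is cut
#' into `L = 2*flank/binSize` bins of binned signal; minus-strand rows are
#' reversed so index 1 is always 5'-most relative to transcription. The TSS
#' sits on the boundary between bins `L/2` and `L/2 + 1`. Windows are
#' aligned to the track's bin grid by flooring the window start to a bin
#' boundary. TSS whose window would cross a chromosome boundary are
#' dropped, with a message giving the count.
#'
#' @param bins a [GenomeBins-class] object.
#' @param tss `GRanges` of width-1 TSS positions (see [readTSS()]).
#' @param flank half-window in bp; must be divisible by the bin size.
#' @return a [ProfileMatrix-class] object.
#' @export
extractProfiles <- function(bins, tss, flank = 5000L) {
  flank <- as.integer(flank)
  bs <- bins@binSize
  if (flank %% bs != 0L) stop("flank must be divisible by binSize")
  L <- 2L * flank %/% bs
  pos <- start(tss) - 1L        # 0-based TSS coordinate
  chrom <- as.character(seqnames(tss))
  chromLen <- bins@seqlengths[chrom]
  b0all <- (pos - flank) %/% bs # grid-aligned first bin of the window
  keep <- !is.na(chromLen) & b0all >= 0L & (b0all + L) * bs <= chromLen
  if (any(!keep))
    message(sum(!keep), " TSS dropped (window out of chromosome bounds)")
  tss <- tss[keep]; pos <- pos[keep]; chrom <- chrom[keep]
  b0all <- b0all[keep]
  M <- length(tss)
  sig <- matrix(0, nrow = M, ncol = L)
  for (j in seq_len(M)) {
    b0 <- b0all[j]
    row <- bins@values[[chrom[j]]][(b0 + 1L):(b0 + L)]
    if (as.character(strand(tss))[j] == "-") row <- rev(row)
    sig[j, ] <- row
  }
  loci <- GRanges(chrom, IRanges(start = pos - flank + 1L, width = 2L * flank),
                  strand = strand(tss))
  mcols(loci)$gene_id <- mcols(tss)$gene_id
  new("ProfileMatrix", markName = bins@markName, signal = sig, loci = loci,
      binSize = bs, flank = flank)
}

#' Stack per-mark profile matrices over a shared locus index
#'
#' @param matrices list of [ProfileMatrix-class] objects with identical loci.
#' @return a [ProfileStack-class] object.
#' @export
stackProfiles <- function(matrices) {
  if (!length(matrices)) stop("empty list of profile matrices")
  ref <- matrices[[1]]@loci
  for (i in seq_along(matrices)[-1]) {
    cur <- matrices[[i]]@loci
    if (length(cur) != length(ref))
      stop(sprintf("locus index mismatch: mark '%s' has %d loci, expected %d",
                   matrices[[i]]@markName, length(cur), length(ref)))
    same <- as.character(seqnames(cur)) == as.character(seqnames(ref)) &
      start(cur) == start(ref) & as.character(strand(cur)) == as.character(strand(ref))
    if (!all(same))
      stop(sprintf("locus index mismatch at row %d between mark '%s' and '%s'",
                   which(!same)[1], matrices[[i]]@markName, matrices[[1]]@markName))
  }
  new("ProfileStack", profiles = matrices)
}

#' Data matrix of vectorized mark profiles
#'
#' Returns the (M*L) x N matrix whose column i is the row-major flattening
#' of mark i's M x L profile matrix — the per-mark profile vectors arranged
#' side by side for self-representation.
#'
#' @param stack a [ProfileStack-class] object.
#' @return numeric matrix with mark-name column names.
#' @export
stackMatrix <- function(stack) {
  cols <- lapply(stack@profiles, function(p) as.numeric(t(p@signal)))
  H <- do.call(cbind, cols)
  colnames(H) <- markNames(stack)
  H
}
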