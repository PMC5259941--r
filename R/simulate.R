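# Synthetic fixture generator with fully known ground truth:
#  - marks fall into planted clusters; within a cluster every mark is a
#    strict linear combination of two shared latent bump profiles (before
#    noise), so the self-representation affinity has block support;
#  - promoter loci fall into K shape classes (distinct bump centers/widths
#    per class, pairwise modified PCC <= 0.3 enforced at generation);
#  - a few "hidden" promoter-patterned loci are planted in intergenic
#    background, half on each strand;
#  - per-gene expression is lognormal with class-dependent location, so the
#    class index doubles as the activity rank.

#' Synthetic-data configuration
#'
#' Defaults define the reference fixture: 12 marks in 4 clusters (3 marks
#' each), 8 promoter shape classes x 250 loci, 10 hidden promoter loci in
#' intergenic background on one synthetic chromosome, ±5 kb promoter
#' windows at 100 bp bins. Signal is on a tag-count-like scale (template
#' peak amplitude ~8 over a 0.5 baseline) and noise is additive Gaussian
#' truncated at zero with standard deviation `noiseSigma x amplitude`.
#'
#' @param nMarks number of marks.
#' @param markClusters integer vector assigning each mark to a cluster.
#' @param nClasses number of promoter shape classes.
#' @param nPromotersPerClass loci per class.
#' @param nHidden hidden promoter loci planted in intergenic background.
#' @param binSize bin width in bp.
#' @param flank promoter half-window in bp (window = 2*flank).
#' @param amplitude template peak amplitude (tag-count scale).
#' @param baseline background signal level.
#' @param noiseSigma noise SD relative to `amplitude`.
#' @param exprMeanlog per-class lognormal location of gene expression,
#'   decreasing from active to poised classes.
#' @param exprSdlog lognormal scale of gene expression.
#' @param chromName name of the synthetic chromosome.
#' @param intergenicLength bp of promoter-free background appended after
#'   the promoter block (hidden loci are planted inside it).
#' @param maxTemplatePCC pairwise modified-PCC ceiling enforced between
#'   class templates.
#' @return a list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nMarks = 12L,
                        markClusters = rep(1:4, each = 3L),
                        nClasses = 8L,
                        nPromotersPerClass = 250L,
                        nHidden = 10L,
                        binSize = 100L,
                        flank = 5000L,
                        amplitude = 8,
                        baseline = 0.5,
                        noiseSigma = 0.1,
                        exprMeanlog = c(4.0, 3.6, 3.2, 2.8, 1.5, 1.2, 0.3, 0.1),
                        exprSdlog = 0.5,
                        chromName = "chrS",
                        intergenicLength = 400000L,
                        maxTemplatePCC = 0.3) {
  stopifnot(length(markClusters) == nMarks,
            length(exprMeanlog) == nClasses,
            flank %% binSize == 0)
  structure(list(
    nMarks = as.integer(nMarks), markClusters = as.integer(markClusters),
    nClasses = as.integer(nClasses),
    nPromotersPerClass = as.integer(nPromotersPerClass),
    nHidden = as.integer(nHidden), binSize = as.integer(binSize),
    flank = as.integer(flank), amplitude = amplitude, baseline = baseline,
    noiseSigma = noiseSigma, exprMeanlog = exprMeanlog, exprSdlog = exprSdlog,
    chromName = chromName, intergenicLength = as.integer(intergenicLength),
    maxTemplatePCC = maxTemplatePCC
  ), class = "SynthConfig")
}

# Gaussian bump over L bins
.bump <- function(L, center, width, amp) {
  amp * exp(-((seq_len(L) - center)^2) / (2 * width^2))
}

# Latent templates: for class c and mark-cluster g, two latents of length L
# (the second is the first shifted by 4 bins). Class centers are spaced 11
# bins apart so distinct classes are near-uncorrelated; per-cluster
# rotation makes every cluster see every shape. Returns list [[c]][[g]] of
# L x 2 matrices; jitter shifts all centers (template-similarity retries).
.synthLatents <- function(config, jitter = 0L) {
  L <- 2L * config$flank %/% config$binSize
  nG <- max(config$markClusters)
  centers <- round(seq(6, by = 11, length.out = config$nClasses) * L / 100) + jitter
  widths <- (2 + 0.25 * seq_len(config$nClasses)) * L / 100
  amps <- config$amplitude * (1.3 - 0.08 * seq_len(config$nClasses))
  lapply(seq_len(config$nClasses), function(cc) {
    lapply(seq_len(nG), function(g) {
      shape <- ((cc - 1L + 2L * (g - 1L)) %% config$nClasses) + 1L
      u1 <- .bump(L, centers[shape], widths[shape], amps[cc])
      u2 <- .bump(L, centers[shape] + 4L, widths[shape], amps[cc])
      cbind(u1, u2)
    })
  })
}

# fixed per-mark mixing weights on the cluster's two latents (position of
# the mark within its cluster decides the row)
.mixWeights <- function(config) {
  base <- matrix(c(1.0, 0.2,
                   0.5, 0.8,
                   0.9, 0.5,
                   0.7, 0.35), ncol = 2, byrow = TRUE)
  within <- stats::ave(seq_along(config$markClusters), config$markClusters,
                       FUN = seq_along)
  base[(within - 1L) %% nrow(base) + 1L, , drop = FALSE]
}

# noiseless per-mark class template matrix: [[class]] -> nMarks x L.
# The background baseline is folded into each latent so every mark stays a
# strict linear combination of its cluster's latents (offset included);
# a baseline shared additively across all marks would put every mark
# outside its cluster's span and leak affinity across clusters.
.markTemplates <- function(config, latents) {
  Wmix <- .mixWeights(config)
  lapply(seq_len(config$nClasses), function(cc) {
    t(vapply(seq_len(config$nMarks), function(i) {
      g <- config$markClusters[i]
      as.numeric((latents[[cc]][[g]] + config$baseline) %*% Wmix[i, ])
    }, numeric(nrow(latents[[cc]][[1]]))))
  })
}

# enforce pairwise modified PCC <= ceiling between concatenated class
# templates, shifting centers by one bin per retry
.validatedLatents <- function(config, attempts = 100L) {
  L <- 2L * config$flank %/% config$binSize
  for (a in seq_len(attempts) - 1L) {
    latents <- .synthLatents(config, jitter = a)
    tpl <- .markTemplates(config, latents)
    flat <- vapply(tpl, function(m) as.numeric(t(m)), numeric(config$nMarks * L))
    ok <- TRUE
    for (i in seq_len(config$nClasses - 1L)) {
      for (j in (i + 1L):config$nClasses) {
        s <- suppressWarnings(as.numeric(
          modifiedPCC(flat[, i], flat[, j], config$nMarks, L)))
        if (is.finite(s) && s > config$maxTemplatePCC) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(latents)
  }
  stop("could not generate class templates with pairwise modified PCC <= ",
       config$maxTemplatePCC, " in ", attempts, " attempts")
}

.truncNoise <- function(n, sigma) stats::rnorm(n, 0, sigma)

#' Simulate a promoter profile stack with planted structure
#'
#' Generates the promoter-level view of the fixture directly: for each
#' locus of a shape class, every mark's profile is its cluster's latent
#' mixture for that class plus truncated-at-zero Gaussian noise. This is
#' the fast path for testing affinity, mark clustering and pattern
#' discovery; [simulateChromatin()] generates the full genome tracks.
#'
#' @param config a [synthConfig()] list.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `stack` ([ProfileStack-class]), `classes` (per-locus
#'   true class), `geneIds`, `expression` (named vector), and
#'   `markClusters` (true mark partition).
#' @export
simulateStack <- function(config = synthConfig(), seed = 1L) {
  old_seed <- .saveSeed(); on.exit(.restoreSeed(old_seed))
  set.seed(as.integer(seed))
  L <- 2L * config$flank %/% config$binSize
  latents <- .validatedLatents(config)
  tpl <- .markTemplates(config, latents)
  M <- config$nClasses * config$nPromotersPerClass
  classes <- sample(rep(seq_len(config$nClasses), config$nPromotersPerClass))
  sigma <- config$noiseSigma * config$amplitude
  geneIds <- sprintf("gene%04d", seq_len(M))
  loci <- GRanges(config$chromName,
                  IRanges(start = (seq_len(M) - 1L) * 2L * config$flank + 1L,
                          width = 2L * config$flank),
                  strand = rep(c("+", "-"), length.out = M))
  mcols(loci)$gene_id <- geneIds
  mats <- lapply(seq_len(config$nMarks), function(i) {
    sig <- matrix(0, M, L)
    for (cc in seq_len(config$nClasses)) {
      rows <- which(classes == cc)
      sig[rows, ] <- rep(tpl[[cc]][i, ], each = length(rows))
    }
    sig <- pmax(sig + matrix(.truncNoise(M * L, sigma), M, L), 0)
    new("ProfileMatrix", markName = sprintf("mark%02d", i), signal = sig,
        loci = loci, binSize = config$binSize, flank = config$flank)
  })
  expression <- stats::setNames(
    stats::rlnorm(M, meanlog = config$exprMeanlog[classes], sdlog = config$exprSdlog),
    geneIds)
  list(stack = stackProfiles(mats), classes = classes, geneIds = geneIds,
       expression = expression, markClusters = config$markClusters)
}

#' Simulate genome tracks with planted promoters and hidden loci
#'
#' Lays the promoter loci head to tail along one synthetic chromosome
#' (each in its own `2*flank` window, alternating strands; minus-strand
#' templates are reversed in genome coordinates), appends an intergenic
#' background segment, and plants `nHidden` active-class promoter loci
#' inside it, half on each strand. Background everywhere is
#' `baseline` + truncated noise.
#'
#' @param config a [synthConfig()] list.
#' @param seed integer seed.
#' @return list with `tracks` (named list of [GenomeBins-class]), `tss`
#'   (`GRanges`), `genes` (`GRanges` gene bodies), `expression` (named
#'   vector) and `truth` (list: `markClusters`, `classes`, `geneIds`,
#'   `hidden` `GRanges` with true class and strand).
#' @export
simulateChromatin <- function(config = synthConfig(), seed = 1L) {
  old_seed <- .saveSeed(); on.exit(.restoreSeed(old_seed))
  set.seed(as.integer(seed))
  L <- 2L * config$flank %/% config$binSize
  win <- 2L * config$flank
  latents <- .validatedLatents(config)
  tpl <- .markTemplates(config, latents)
  M <- config$nClasses * config$nPromotersPerClass
  classes <- sample(rep(seq_len(config$nClasses), config$nPromotersPerClass))
  strands <- rep(c("+", "-"), length.out = M)
  geneIds <- sprintf("gene%04d", seq_len(M))
  sigma <- config$noiseSigma * config$amplitude

  # hidden loci: inside the intergenic tail, spaced three windows apart
  hidden_classes <- rep(seq_len(min(4L, config$nClasses)),
                        length.out = config$nHidden)
  hidden_strands <- rep(c("+", "-"), length.out = config$nHidden)
  hidden_off <- M * win + seq_len(config$nHidden) * 3L * win  # 0-based starts
  chromLen <- M * win + config$intergenicLength +
    (config$nHidden * 3L + 2L) * win
  nb <- chromLen %/% config$binSize
  chromSizes <- stats::setNames(chromLen, config$chromName)

  tracks <- lapply(seq_len(config$nMarks), function(i) {
    v <- pmax(config$baseline + .truncNoise(nb, sigma), 0)
    for (j in seq_len(M)) {
      tprof <- tpl[[classes[j]]][i, ]
      if (strands[j] == "-") tprof <- rev(tprof)
      b0 <- (j - 1L) * L
      v[(b0 + 1L):(b0 + L)] <- pmax(v[(b0 + 1L):(b0 + L)] + tprof, 0)
    }
    for (h in seq_len(config$nHidden)) {
      tprof <- tpl[[hidden_classes[h]]][i, ]
      if (hidden_strands[h] == "-") tprof <- rev(tprof)
      b0 <- hidden_off[h] %/% config$binSize
      v[(b0 + 1L):(b0 + L)] <- pmax(v[(b0 + 1L):(b0 + L)] + tprof, 0)
    }
    genomeBins(sprintf("mark%02d", i), stats::setNames(list(v), config$chromName),
               chromSizes, config$binSize)
  })
  names(tracks) <- vapply(tracks, markNames, character(1))

  tss_pos <- (seq_len(M) - 1L) * win + config$flank   # 0-based, window centers
  tss <- GRanges(config$chromName, IRanges(start = tss_pos + 1L, width = 1L),
                 strand = strands)
  mcols(tss)$gene_id <- geneIds
  gene_len <- 3000L
  gstart <- ifelse(strands == "+", tss_pos, tss_pos - gene_len)
  genes <- GRanges(config$chromName,
                   IRanges(start = gstart + 1L, width = gene_len),
                   strand = strands)
  mcols(genes)$gene_id <- geneIds
  expression <- stats::setNames(
    stats::rlnorm(M, meanlog = config$exprMeanlog[classes], sdlog = config$exprSdlog),
    geneIds)
  hidden <- GRanges(config$chromName,
                    IRanges(start = hidden_off + 1L, width = win),
                    strand = hidden_strands)
  mcols(hidden)$class <- hidden_classes
  list(tracks = tracks, tss = tss, genes = genes, expression = expression,
       truth = list(markClusters = config$markClusters, classes = classes,
                    geneIds = geneIds, hidden = hidden))
}

#' Write a simulated fixture to standard files
#'
#' Emits one bedGraph per mark, `tss.bed` (BED6), `genes.bed` (BED12 with a
#' single block per gene), `expression.tsv`, `chrom.sizes` and
#' `truth.json`.
#'
#' @param sim output of [simulateChromatin()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(sim$tracks))
    writeBedGraph(sim$tracks[[m]], file.path(dir, paste0(m, ".bedGraph")))
  tss <- sim$tss
  utils::write.table(
    data.frame(chrom = as.character(seqnames(tss)), start = start(tss) - 1L,
               end = end(tss), name = mcols(tss)$gene_id, score = 0,
               strand = as.character(strand(tss))),
    file.path(dir, "tss.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  g <- sim$genes
  utils::write.table(
    data.frame(chrom = as.character(seqnames(g)), start = start(g) - 1L,
               end = end(g), name = mcols(g)$gene_id, score = 0,
               strand = as.character(strand(g)), thickStart = start(g) - 1L,
               thickEnd = end(g), rgb = 0, blockCount = 1L,
               blockSizes = GenomicRanges::width(g), blockStarts = 0L),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(sim$expression), value = unname(sim$expression)),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  bins1 <- sim$tracks[[1]]
  utils::write.table(
    data.frame(chrom = names(bins1@seqlengths), length = unname(bins1@seqlengths)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  hid <- sim$truth$hidden
  jsonlite::write_json(list(
    markClusters = sim$truth$markClusters,
    classes = sim$truth$classes,
    geneIds = sim$truth$geneIds,
    hidden = data.frame(chrom = as.character(seqnames(hid)),
                        start = start(hid) - 1L, end = end(hid),
                        strand = as.character(strand(hid)),
                        class = mcols(hid)$class)
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score pipeline outputs against the planted truth
#'
#' @param truth the `truth` element of [simulateChromatin()] (or the
#'   analogous fields of [simulateStack()]).
#' @param clustering optional [MarkClustering-class]: scored as adjusted
#'   Rand index against the planted mark partition.
#' @param model optional [PatternModel-class]: scored as the per-locus
#'   label agreement with the planted classes after optimal one-to-one
#'   matching of cluster ids.
#' @param hits optional `GRanges` of scan hits: hidden-promoter recall
#'   (planted locus counted recovered when some hit covers >= 50% of it)
#'   and precision over hits outside annotated promoter windows (`tss`
#'   plus `flank` required for that masking).
#' @param tss,flank annotation used to restrict precision to novel hits.
#' @return list of the computed metrics (only those requested).
#' @export
evaluateRecovery <- function(truth, clustering = NULL, model = NULL,
                             hits = NULL, tss = NULL, flank = 5000L) {
  out <- list()
  if (!is.null(clustering)) {
    out$markClusterARI <-
      mclust::adjustedRandIndex(truth$markClusters, unname(clustering@assignment))
  }
  if (!is.null(model)) {
    out$patternAgreement <- labelAgreement(truth$classes, model@labels)
  }
  if (!is.null(hits)) {
    hid <- truth$hidden
    if (length(hits)) {
      ov <- GenomicRanges::findOverlaps(hid, hits, ignore.strand = TRUE)
      ow <- GenomicRanges::width(GenomicRanges::pintersect(
        hid[S4Vectors::queryHits(ov)], hits[S4Vectors::subjectHits(ov)],
        ignore.strand = TRUE))
      good <- ow >= 0.5 * GenomicRanges::width(hid[S4Vectors::queryHits(ov)])
      recovered <- unique(S4Vectors::queryHits(ov)[good])
      out$hiddenRecall <- length(recovered) / length(hid)
      novel <- hits
      if (!is.null(tss) && length(tss)) {
        prom <- suppressWarnings(GenomicRanges::resize(
          tss, width = 2L * flank, fix = "center", ignore.strand = TRUE))
        novel <- hits[!IRanges::overlapsAny(hits, prom, ignore.strand = TRUE)]
      }
      if (length(novel)) {
        tp <- IRanges::overlapsAny(novel, hid, ignore.strand = TRUE,
                                   minoverlap = as.integer(0.5 * min(GenomicRanges::width(hid))))
        out$hiddenPrecision <- mean(tp)
      } else out$hiddenPrecision <- NA_real_
    } else {
      out$hiddenRecall <- 0
      out$hiddenPrecision <- NA_real_
    }
  }
  out
}

#' Per-locus label agreement after optimal cluster matching
#'
#' Maximizes, over one-to-one matchings of predicted to true cluster ids,
#' the fraction of loci whose matched label equals the truth. Exhaustive
#' over permutations (supported up to 8 clusters on the smaller side).
#'
#' @param truth,labels integer vectors of equal length.
#' @return agreement fraction in `[0, 1]`.
#' @export
labelAgreement <- function(truth, labels) {
  stopifnot(length(truth) == length(labels))
  tl <- sort(unique(truth)); pl <- sort(unique(labels))
  tab <- table(factor(truth, levels = tl), factor(labels, levels = pl))
  small_pred <- length(pl) <= length(tl)
  kS <- min(length(tl), length(pl)); kL <- max(length(tl), length(pl))
  if (kS > 8L) stop("optimal matching supported up to 8 clusters")
  ii <- seq_len(kS)
  if (kS == kL) {
    P <- .permMatrix(kL)
    # linear indices into tab for each permutation row
    lin <- if (small_pred) P + matrix((ii - 1L) * nrow(tab), nrow(P), kS, byrow = TRUE)
           else matrix(rep(ii, each = nrow(P)), nrow(P)) + (P - 1L) * nrow(tab)
    best <- max(rowSums(matrix(tab[as.vector(lin)], nrow(P))))
  } else {
    best <- 0
    for (perm in .permutations(kL, kS)) {
      tot <- if (small_pred) sum(tab[cbind(perm, ii)]) else sum(tab[cbind(ii, perm)])
      if (tot > best) best <- tot
    }
  }
  best / length(truth)
}
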