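# A small planted model for direct scan tests: 2 marks, L = 10 bins.
plantedModel <- function() {
  L <- 10L
  c1 <- c(dnorm(1:10, 4, 1.2), dnorm(1:10, 7, 1.5)) * 40
  c2 <- c(seq(0, 9), seq(9, 0)) * 2
  new("PatternModel", centroids = rbind(c(c1), c(c2)),
      labels = c(1L, 2L), markNames = c("mA", "mB"), L = L,
      seed = 1L, patternOrder = 1:2, totWithinSS = 0)
}

plantedTracks <- function(model, nb = 200L, plantAt = c(40L), pattern = 1L,
                          strandOf = "+", noise = 0, seed = 99) {
  set.seed(seed)
  L <- model@L
  lapply(setNames(seq_along(model@markNames), model@markNames), function(b) {
    v <- pmax(rnorm(nb, 0.5, max(noise, 1e-3)), 0)
    for (i in seq_along(plantAt)) {
      blk <- model@centroids[pattern[min(i, length(pattern))],
                             ((b - 1) * L + 1):(b * L)]
      if (strandOf[min(i, length(strandOf))] == "-") blk <- rev(blk)
      v[(plantAt[i] + 1):(plantAt[i] + L)] <- blk + 0.5
    }
    toyBins(v, markName = names(setNames(seq_along(model@markNames),
                                         model@markNames))[b], binSize = 100L)
  })
}

test_that("an exactly planted pattern is found with per-mark PCC 1", {
  model <- plantedModel()
  tracks <- plantedTracks(model, plantAt = 40L, pattern = 1L)
  cfg <- scanConfig(window = 1000L, step = 200L, threshold = 0.75,
                    patterns = 1:2)
  hits <- scanGenome(tracks, model, cfg)
  exact <- hits[start(hits) - 1L == 4000 & strand(hits) == "+"]
  expect_equal(length(exact), 1)
  expect_equal(S4Vectors::mcols(exact)$pattern, 1L)
  expect_equal(S4Vectors::mcols(exact)$minPCC, 1, tolerance = 1e-12)
  expect_equal(S4Vectors::mcols(exact)$meanPCC, 1, tolerance = 1e-12)
})

test_that("flat chromosomes yield no hits, only skipped windows", {
  model <- plantedModel()
  tracks <- lapply(setNames(c("mA", "mB"), c("mA", "mB")), function(m)
    toyBins(rep(2, 200), markName = m))
  cfg <- scanConfig(window = 1000L, step = 200L, patterns = 1:2)
  hits <- scanGenome(tracks, model, cfg)
  expect_equal(length(hits), 0)
  expect_gt(S4Vectors::metadata(hits)$skipped, 0)
})

test_that("window geometry is validated", {
  model <- plantedModel()
  tracks <- plantedTracks(model)
  expect_error(scanGenome(tracks, model, scanConfig(window = 1050L)),
               "multiple")
  expect_error(scanGenome(tracks, model, scanConfig(window = 2000L)),
               "L = 10")
})

test_that("scan equals the naive double-loop reference on noisy plants", {
  model <- plantedModel()
  tracks <- plantedTracks(model, nb = 300L, plantAt = c(20L, 120L, 240L),
                          pattern = c(1L, 2L, 1L), strandOf = c("+", "-", "+"),
                          noise = 0.25, seed = 7)
  cfg <- scanConfig(window = 1000L, step = 200L, threshold = 0.75,
                    patterns = 1:2)
  hits <- scanGenome(tracks, model, cfg)
  ref <- naiveScan(tracks, model, window = 1000L, step = 200L,
                   threshold = 0.75, patterns = 1:2)
  expect_equal(hitsToFrame(hits), ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_gte(length(hits), 3)
})

test_that("raising the threshold never adds hits", {
  model <- plantedModel()
  tracks <- plantedTracks(model, nb = 300L, plantAt = c(20L, 120L, 240L),
                          pattern = c(1L, 2L, 1L), noise = 0.4, seed = 13)
  key <- function(h) paste(start(h), strand(h))
  h75 <- scanGenome(tracks, model, scanConfig(window = 1000L, step = 200L,
                                              threshold = 0.75, patterns = 1:2))
  h85 <- scanGenome(tracks, model, scanConfig(window = 1000L, step = 200L,
                                              threshold = 0.85, patterns = 1:2))
  expect_true(all(key(h85) %in% key(h75)))
})

test_that("reversing the tracks mirrors hits onto the other strand", {
  model <- plantedModel()
  tracks <- plantedTracks(model, nb = 200L, plantAt = 40L, pattern = 1L,
                          noise = 0.2, seed = 5)
  cfg <- scanConfig(window = 1000L, step = 200L, threshold = 0.75,
                    patterns = 1:2)
  hits <- scanGenome(tracks, model, cfg)
  rev_tracks <- lapply(tracks, function(b) {
    b@values <- lapply(b@values, rev); b
  })
  rhits <- scanGenome(rev_tracks, model, cfg)
  nb <- 200L; wb <- 10L
  mirror <- function(start_bin) nb - wb - start_bin
  flip <- c(`+` = "-", `-` = "+")
  key <- function(s_bin, st) paste(s_bin, st)
  expect_setequal(key(mirror((start(hits) - 1L) %/% 100L),
                      flip[as.character(strand(hits))]),
                  key((start(rhits) - 1L) %/% 100L, as.character(strand(rhits))))
})

test_that("merging keeps the best window of each overlapping run", {
  model <- plantedModel()
  # low threshold so several consecutive overlapping windows fire
  tracks <- plantedTracks(model, nb = 200L, plantAt = 40L, pattern = 1L,
                          noise = 0.05, seed = 3)
  cfg <- scanConfig(window = 1000L, step = 200L, threshold = 0.10,
                    patterns = 1L, strands = "+")
  hits <- scanGenome(tracks, model, cfg)
  expect_gt(length(hits), 1)
  merged <- mergeHits(hits)
  plant <- GRanges("chr1", IRanges(4001, width = 1000))
  run <- merged[IRanges::overlapsAny(merged, plant)]
  overlapping <- hits[IRanges::overlapsAny(hits, plant)]
  expect_gt(length(overlapping), 1)   # several consecutive windows fired
  # enumeration: the one surviving window is the best-scoring, the plant
  expect_equal(length(run), 1)
  expect_equal(start(run) - 1L, 4000L)
  expect_equal(S4Vectors::mcols(run)$meanPCC,
               max(S4Vectors::mcols(overlapping)$meanPCC))
  # disjoint hits unchanged; "none" mode is the identity
  expect_identical(length(mergeHits(hits, mode = "none")), length(hits))
})

test_that("opposite strands and different patterns are never merged", {
  gr <- GRanges("chr1", IRanges(c(1, 501, 1001), width = 1000),
                strand = c("+", "-", "+"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(pattern = c(1L, 1L, 1L),
                                               minPCC = c(.8, .8, .9),
                                               meanPCC = c(.85, .9, .95))
  m <- mergeHits(gr)
  expect_equal(length(m), 3)   # +/- overlap not merged; +/+ disjoint-ish?
  gr2 <- GRanges("chr1", IRanges(c(1, 501), width = 1000), strand = "+")
  S4Vectors::mcols(gr2) <- S4Vectors::DataFrame(pattern = c(1L, 2L),
                                                minPCC = c(.8, .8),
                                                meanPCC = c(.85, .9))
  expect_equal(length(mergeHits(gr2)), 2)
})

test_that("hit classification matches manual interval arithmetic", {
  hits <- GRanges("chr1", IRanges(c(1, 20001, 40001, 60001, 80001, 100001),
                                  width = 10000), strand = "+")
  S4Vectors::mcols(hits) <- S4Vectors::DataFrame(
    pattern = c(1L, 1L, 2L, 2L, 1L, 2L),
    minPCC = rep(.8, 6), meanPCC = rep(.9, 6))
  tss <- GRanges("chr1", IRanges(c(5000, 62000), width = 1),
                 strand = "+")
  S4Vectors::mcols(tss)$gene_id <- c("gA", "gB")
  genes <- GRanges("chr1", IRanges(c(5000, 42000, 62000), width = 8000),
                   strand = "+")
  out <- classifyHits(hits, tss, genes, flank = 5000)
  cls <- S4Vectors::mcols(out$hits)$annotation
  # manual: hit1 contains TSS gA; hit3 inside gene2 body; hit4 contains TSS gB;
  # hits 2,5,6 hit nothing
  expect_equal(cls, c("overlaps_annotation", "unannotated_between_genes",
                      "unannotated_within_gene", "overlaps_annotation",
                      "unannotated_between_genes", "unannotated_between_genes"))
  expect_equal(sum(out$summary), 6)
  expect_equal(out$summary["1", "overlaps_annotation"], 1)
  expect_equal(out$summary["2", "unannotated_within_gene"], 1)
  # empty annotation warns
  expect_warning(classifyHits(hits, GRanges(), GRanges()), "empty annotation")
})
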