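# End-to-end orchestration: bin -> profiles -> affinity (+ lambda
# selection) -> mark clustering & representatives -> patterns -> scan,
# with a manifest recording parameters, seed and output hashes so reruns
# with identical inputs are bit-identical.

#' Build a pipeline run configuration
#'
#' @param tracks named character vector/list: mark -> signal track path for
#'   the primary dataset.
#' @param tss path to the BED6 TSS list.
#' @param chromSizes path to a two-column chrom.sizes file.
#' @param outDir output directory.
#' @param tracks2 optional second dataset (same mark names); required for
#'   lambda selection by cross-dataset concordance and for choosing the
#'   mark-cluster count by overlap.
#' @param genes optional gene-body BED for hit classification.
#' @param expression optional two-column TSV `gene_id`, `value` for pattern
#'   ranking.
#' @param binSize,flank binning resolution and promoter half-window (bp).
#' @param lambda fixed penalty; ignored when `lambdaGrid` is given.
#' @param lambdaGrid optional grid for [selectLambda()] (needs `tracks2`).
#' @param kMarks fixed mark-cluster count; ignored when `kMarksGrid` given.
#' @param kMarksGrid optional grid for [chooseKMarks()] (needs `tracks2`).
#' @param representatives optional explicit representative marks.
#' @param kPatterns number of promoter patterns.
#' @param scan a [scanConfig()] object.
#' @param seed master seed; every stochastic stage derives from it.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(tracks, tss, chromSizes, outDir,
                      tracks2 = NULL, genes = NULL, expression = NULL,
                      binSize = 100L, flank = 5000L,
                      lambda = NULL, lambdaGrid = NULL,
                      kMarks = 4L, kMarksGrid = NULL,
                      representatives = NULL, kPatterns = 8L,
                      scan = scanConfig(), seed = 1L) {
  cfg <- list(tracks = tracks, tss = tss, chromSizes = chromSizes,
              outDir = outDir, tracks2 = tracks2, genes = genes,
              expression = expression, binSize = as.integer(binSize),
              flank = as.integer(flank), lambda = lambda,
              lambdaGrid = lambdaGrid, kMarks = as.integer(kMarks),
              kMarksGrid = kMarksGrid, representatives = representatives,
              kPatterns = as.integer(kPatterns), scan = scan,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Accepts the same fields as [runConfig()]; the `scan` entry may be a
#' mapping with `window`, `step`, `threshold`, `strands`, `patterns`.
#'
#' @param path YAML file.
#' @return a `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("tracks", "tss", "chromSizes", "outDir"))
    if (is.null(y[[f]])) stop("run config is missing required field '", f, "'")
  sc <- y$scan %||% list()
  y$scan <- scanConfig(window = sc$window %||% 10000L, step = sc$step %||% 2000L,
                       threshold = sc$threshold %||% 0.75,
                       strands = sc$strands %||% "both",
                       patterns = sc$patterns)
  do.call(runConfig, y[intersect(names(y), names(formals(runConfig)))])
}

.checkPaths <- function(config) {
  one <- function(field, p) {
    if (!is.null(p) && !all(file.exists(unlist(p))))
      stop("run config field '", field, "' names a missing file")
  }
  for (f in c("tracks", "tss", "chromSizes", "tracks2", "genes", "expression"))
    one(f, config[[f]])
}

.loadDataset <- function(tracks, chromSizes, binSize) {
  bins <- lapply(names(tracks), function(m)
    readSignalTrack(tracks[[m]], chromSizes, binSize = binSize, markName = m))
  names(bins) <- names(tracks)
  bins
}

#' Run the full discovery workflow
#'
#' Executes binning, promoter-profile extraction, sparse
#' self-representation (with lambda selection when a grid and second
#' dataset are given), mark clustering and representative selection,
#' pattern discovery (with expression ranking when available) and the
#' genome scan, writing every stage output plus a `manifest.json` under
#' `config$outDir`. The manifest lists stage parameters, the seed, and an
#' md5 for each output file; reruns with identical inputs and seed produce
#' identical manifests. Any stage error halts the run with the stage name;
#' outputs of completed stages are retained.
#'
#' @param config a `"RunConfig"` from [runConfig()] / [readRunConfig()].
#' @return list with the in-memory stage results (`bins`, `stack`,
#'   `affinity`, `lambdaScan`, `clustering`, `model`, `hits`, `classified`,
#'   `manifest`), invisibly.
#' @export
runAll <- function(config) {
  stage <- "validate"
  result <- list()
  manifest <- list(seed = config$seed,
                   parameters = list(binSize = config$binSize, flank = config$flank,
                                     kPatterns = config$kPatterns),
                   inputs = list(), stages = list(), outputs = list())
  tryCatch({
    .checkPaths(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    infiles <- c(unlist(config$tracks), config$tss, config$chromSizes,
                 unlist(config$tracks2), config$genes, config$expression)
    manifest$inputs <- as.list(tools::md5sum(unlist(infiles)))

    stage <- "bin"
    chromSizes <- readChromSizes(config$chromSizes)
    bins1 <- .loadDataset(config$tracks, chromSizes, config$binSize)
    bins2 <- if (!is.null(config$tracks2))
      .loadDataset(config$tracks2, chromSizes, config$binSize) else NULL
    manifest$stages$bin <- list(marks = names(bins1),
                                datasets = if (is.null(bins2)) 1L else 2L)

    stage <- "profiles"
    tss <- readTSS(config$tss)
    stack1 <- stackProfiles(lapply(bins1, extractProfiles, tss = tss,
                                   flank = config$flank))
    stack2 <- if (!is.null(bins2))
      stackProfiles(lapply(bins2, extractProfiles, tss = tss,
                           flank = config$flank)) else NULL
    manifest$stages$profiles <- list(loci = nLoci(stack1), L = profileLength(stack1))

    stage <- "affinity"
    lambdaScan <- NULL
    if (!is.null(config$lambdaGrid)) {
      if (is.null(stack2)) stop("lambdaGrid requires a second dataset (tracks2)")
      lambdaScan <- selectLambda(stack1, stack2, config$lambdaGrid)
      lambda <- lambdaScan@chosen
      utils::write.table(lambdaScan@table, file.path(config$outDir, "lambda_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      lambda <- config$lambda %||% stop("either lambda or lambdaGrid must be set")
    }
    A1 <- solveSelfRepresentation(stack1, lambda)
    writeAffinity(A1, file.path(config$outDir, "affinity.tsv"))
    A2 <- if (!is.null(stack2)) solveSelfRepresentation(stack2, lambda) else NULL
    manifest$stages$affinity <- list(lambda = lambda,
                                     lambdaSelected = !is.null(lambdaScan))

    stage <- "cluster_marks"
    if (!is.null(config$kMarksGrid)) {
      if (is.null(A2)) stop("kMarksGrid requires a second dataset (tracks2)")
      kChoice <- chooseKMarks(A1, A2, config$kMarksGrid)
      kMarks <- kChoice$bestK
    } else kMarks <- config$kMarks
    clustering <- clusterMarks(A1, kMarks)
    clustering <- selectRepresentatives(A1, clustering,
                                        override = config$representatives)
    writeClustering(clustering, file.path(config$outDir, "clusters.json"))
    manifest$stages$cluster_marks <- list(K = kMarks,
                                          representatives = representatives(clustering))

    stage <- "patterns"
    X <- concatenateProfiles(stack1, representatives(clustering))
    model <- fitPatterns(X, config$kPatterns, seed = config$seed)
    if (!is.null(config$expression)) {
      expr <- utils::read.table(config$expression, sep = "\t", header = FALSE,
                                col.names = c("gene_id", "value"))
      geneIds <- mcols(profileLoci(stack1))$gene_id
      model <- rankByExpression(model, expr, geneIds)
    }
    writePatternModel(model, file.path(config$outDir, "patterns.json"))
    manifest$stages$patterns <- list(K = config$kPatterns, seed = config$seed,
                                     totWithinSS = model@totWithinSS)

    stage <- "scan"
    reps <- representatives(clustering)
    hits <- scanGenome(bins1[reps], model, config$scan)
    merged <- mergeHits(hits)
    classified <- NULL
    if (!is.null(config$genes)) {
      genes <- rtracklayer::import(config$genes, format = "BED")
      classified <- classifyHits(merged, tss, genes, flank = config$flank)
      merged <- classified$hits
      utils::write.table(cbind(pattern = rownames(classified$summary),
                               classified$summary),
                         file.path(config$outDir, "hit_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeHitsBed(merged, file.path(config$outDir, "hits.bed"))
    manifest$stages$scan <- list(window = config$scan@window, step = config$scan@step,
                                 threshold = config$scan@threshold,
                                 strands = config$scan@strands,
                                 nHits = length(merged),
                                 skipped = S4Vectors::metadata(hits)$skipped)

    outs <- list.files(config$outDir, full.names = TRUE)
    outs <- outs[basename(outs) != "manifest.json"]
    manifest$outputs <- as.list(tools::md5sum(outs))
    names(manifest$outputs) <- basename(outs)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result <- list(bins = bins1, stack = stack1, affinity = A1,
                   lambdaScan = lambdaScan, clustering = clustering,
                   model = model, hits = hits, merged = merged,
                   classified = classified, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
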