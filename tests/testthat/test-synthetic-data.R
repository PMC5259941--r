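test_that("generation is deterministic and internally consistent", {
  cfg <- synthConfig(nPromotersPerClass = 10L, nHidden = 4L,
                     intergenicLength = 50000L)
  sim1 <- simulateChromatin(cfg, seed = 7)
  sim2 <- simulateChromatin(cfg, seed = 7)
  expect_identical(sim1$tracks[[1]]@values, sim2$tracks[[1]]@values)
  expect_identical(sim1$truth$classes, sim2$truth$classes)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(sim1, d1); writeSimulation(sim2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the draw
  sim3 <- simulateChromatin(cfg, seed = 8)
  expect_false(identical(sim1$tracks[[1]]@values, sim3$tracks[[1]]@values))
})

test_that("profiles extracted from tracks equal the planted stack view", {
  cfg <- synthConfig(nPromotersPerClass = 10L, nHidden = 2L, noiseSigma = 0,
                     intergenicLength = 30000L)
  sim <- simulateChromatin(cfg, seed = 5)
  pm <- extractProfiles(sim$tracks[["mark01"]], sim$tss, flank = 5000)
  expect_equal(nLoci(pm), 80)
  # strand-aware extraction must recover the oriented class template:
  # loci of one class have identical noiseless profiles regardless of strand
  for (cc in c(1, 5)) {
    rows <- which(sim$truth$classes == cc)
    prof <- pm@signal[rows, , drop = FALSE]
    expect_lt(max(apply(prof, 2, function(x) diff(range(x)))), 1e-9)
  }
})

test_that("noiseless fixtures give affinity support only within planted clusters", {
  cfg <- synthConfig(nPromotersPerClass = 10L, noiseSigma = 0)
  sim <- simulateStack(cfg, seed = 2)
  A <- solveSelfRepresentation(sim$stack, lambda = 1)
  W <- abs(A@coefficients)
  cross <- outer(sim$markClusters, sim$markClusters, `!=`)
  expect_lt(max(W[cross]), 1e-6 * max(W))
  # and within-cluster coefficients are substantial
  within <- outer(sim$markClusters, sim$markClusters, `==`); diag(within) <- FALSE
  expect_gt(max(W[within]), 0.1)
})

test_that("class templates respect the pairwise similarity ceiling", {
  cfg <- synthConfig(nPromotersPerClass = 2L, noiseSigma = 0)
  sim <- simulateStack(cfg, seed = 3)
  # reconstruct per-class noiseless concatenated templates from the stack
  X <- concatenateProfiles(sim$stack, markNames(sim$stack))
  for (i in 1:(cfg$nClasses - 1)) {
    for (j in (i + 1):cfg$nClasses) {
      ri <- which(sim$classes == i)[1]; rj <- which(sim$classes == j)[1]
      s <- suppressWarnings(as.numeric(
        modifiedPCC(X[ri, ], X[rj, ], cfg$nMarks, 100)))
      expect_lte(s, cfg$maxTemplatePCC + 1e-6)
    }
  }
})

test_that("recovery metrics match hand counts on a constructed example", {
  hidden <- GRanges("chrS", IRanges(c(1001, 20001, 40001), width = 1000),
                    strand = c("+", "-", "+"))
  S4Vectors::mcols(hidden)$class <- c(1L, 2L, 1L)
  truth <- list(markClusters = rep(1:2, each = 2), classes = c(1L, 1L, 2L, 2L),
                geneIds = paste0("g", 1:4), hidden = hidden)
  # hits: one covers hidden1 fully, one covers 40% of hidden2, one false
  hits <- GRanges("chrS", IRanges(c(1001, 20401, 90001), width = c(1000, 400, 1000)),
                  strand = "+")
  S4Vectors::mcols(hits) <- S4Vectors::DataFrame(pattern = c(1L, 1L, 2L),
                                                 minPCC = rep(.8, 3),
                                                 meanPCC = rep(.9, 3))
  ev <- evaluateRecovery(truth, hits = hits)
  expect_equal(ev$hiddenRecall, 1 / 3)        # only hidden1 covered >= 50%
  expect_equal(ev$hiddenPrecision, 1 / 3)     # 1 of 3 hits is a true positive
  # perfect clustering and labels
  cl <- new("MarkClustering",
            assignment = setNames(rep(1:2, each = 2), paste0("m", 1:4)),
            representatives = character(), tree = NULL, K = 2L)
  model <- new("PatternModel", centroids = matrix(0, 2, 10),
               labels = c(2L, 2L, 1L, 1L), markNames = "m", L = 10L,
               seed = 1L, patternOrder = 1:2, totWithinSS = 0)
  ev2 <- evaluateRecovery(truth, clustering = cl, model = model)
  expect_equal(ev2$markClusterARI, 1)
  expect_equal(ev2$patternAgreement, 1)       # labels are a relabeling
  # empty hit list: zero recall, precision not applicable
  ev3 <- evaluateRecovery(truth, hits = GRanges())
  expect_equal(ev3$hiddenRecall, 0)
  expect_true(is.na(ev3$hiddenPrecision))
})

test_that("label agreement equals hand counts under partial overlap", {
  truth <- c(1, 1, 1, 2, 2, 2)
  pred <- c(1, 1, 2, 2, 2, 1)
  # best matching keeps ids aligned: 2 + 2 correct of 6
  expect_equal(labelAgreement(truth, pred), 4 / 6)
  expect_equal(labelAgreement(truth, c(2, 2, 2, 1, 1, 1)), 1)
})

test_that("recovery degrades as noise grows", {
  agree <- vapply(c(0.05, 0.6, 2.0), function(sg) {
    sims <- vapply(1:3, function(s) {
      sim <- simulateStack(synthConfig(nPromotersPerClass = 25L, noiseSigma = sg),
                           seed = s)
      X <- concatenateProfiles(sim$stack, c("mark01", "mark04", "mark07", "mark10"))
      labelAgreement(sim$classes, fitPatterns(X, 8, seed = s)@labels)
    }, numeric(1))
    mean(sims)
  }, numeric(1))
  expect_true(agree[1] >= agree[2] && agree[2] >= agree[3])
  expect_gt(agree[1], 0.95)
})
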