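test_that("concatenation preserves block order and length", {
  sim <- simulateStack(synthConfig(nPromotersPerClass = 5L), seed = 8)
  reps <- c("mark01", "mark04", "mark07", "mark10")
  X <- concatenateProfiles(sim$stack, reps)
  expect_equal(ncol(X), 4 * 100)
  expect_equal(attr(X, "markNames"), reps)
  # single mark: rows equal that mark's profiles
  X1 <- concatenateProfiles(sim$stack, "mark02")
  expect_equal(unclass(X1), sim$stack$mark02@signal, ignore_attr = TRUE)
  # permuting representatives permutes blocks
  Xp <- concatenateProfiles(sim$stack, rev(reps))
  expect_equal(unname(Xp[, 1:100]), unname(X[, 301:400]))
  expect_error(concatenateProfiles(sim$stack, "nope"), "unknown")
})

test_that("K-means recovers planted templates and handles edge cases", {
  set.seed(12)
  # 3 well-separated templates, 60 rows
  tpl <- rbind(c(rep(10, 5), rep(0, 5)), c(rep(0, 5), rep(10, 5)),
               c(rep(5, 10)))
  X <- tpl[rep(1:3, each = 20), ] + matrix(rnorm(600, 0, 0.3), 60, 10)
  m <- fitPatterns(X, 3, seed = 4)
  expect_gte(labelAgreement(rep(1:3, each = 20), m@labels), 0.99)
  # duplicate rows always co-clustered
  Xd <- rbind(X, X[1, ], X[1, ])
  md <- fitPatterns(Xd, 3, seed = 4)
  expect_equal(md@labels[61], md@labels[62])
  # K = M: every row its own cluster, zero distance
  mm <- fitPatterns(X[1:5, ], 5, seed = 1)
  expect_equal(mm@totWithinSS, 0)
  expect_equal(sort(mm@labels), 1:5)
})

test_that("fit is deterministic given the seed and matches stats::kmeans quality", {
  set.seed(33)
  X <- matrix(rnorm(200 * 12), 200, 12)
  m1 <- fitPatterns(X, 4, seed = 9)
  m2 <- fitPatterns(X, 4, seed = 9)
  expect_identical(m1@labels, m2@labels)
  expect_identical(m1@centroids, m2@centroids)
  # independent implementation cross-check: objective within 1%
  km <- stats::kmeans(X, 4, nstart = 10, iter.max = 100)
  expect_lte(m1@totWithinSS, km$tot.withinss * 1.01)
})

test_that("silhouette diagnostics separate a 2-blob fixture", {
  set.seed(21)
  X <- rbind(matrix(rnorm(300, 0, 0.5), 30, 10),
             matrix(rnorm(300, 8, 0.5), 30, 10))
  d <- diagnoseK(X, 2:4, seed = 5)
  expect_equal(d$K, 2:4)
  expect_gt(d$silhouette[1], d$silhouette[2])
  expect_true(all(diff(d$totWithinSS) <= 1e-8))
  # degenerate input: identical rows
  Xd <- matrix(1, 10, 5)
  expect_warning(dd <- diagnoseK(Xd, 2, seed = 1), "silhouette undefined")
  expect_true(is.na(dd$silhouette))
})

test_that("modified PCC matches its definition, block by block", {
  set.seed(14)
  L <- 5
  # three identical blocks and one negated block -> (1+1+1-1)/4 = 0.5
  b <- rnorm(L)
  p <- c(b, b, b, b)
  q <- c(b, b, b, 2 * mean(b) - b)   # negate around the mean: cor = -1
  expect_equal(as.numeric(modifiedPCC(p, q, 4, L)), 0.5)
  # identity
  expect_equal(as.numeric(modifiedPCC(p, p, 4, L)), 1.0)
  # random vectors match the direct-formula oracle; symmetric; bounded
  for (i in 1:5) {
    u <- rnorm(4 * L); v <- rnorm(4 * L)
    s <- as.numeric(modifiedPCC(u, v, 4, L))
    expect_equal(s, modifiedPCCOracle(u, v, 4, L))
    expect_equal(s, as.numeric(modifiedPCC(v, u, 4, L)))
    expect_true(s >= -1 && s <= 1)
  }
  # invariance to positive affine rescaling per block
  u <- rnorm(4 * L)
  v <- unlist(lapply(1:4, function(b) 3 * u[((b-1)*L+1):(b*L)] + 7))
  expect_equal(as.numeric(modifiedPCC(u, v, 4, L)), 1.0)
  # zero-variance block excluded with warning
  pz <- c(rep(1, L), b, b, b); qz <- c(rep(2, L), b, b, b)
  expect_warning(sz <- modifiedPCC(pz, qz, 4, L), "zero-variance")
  expect_equal(as.numeric(sz), 1.0)
  expect_equal(attr(sz, "excluded"), 1L)
  expect_error(modifiedPCC(u, v[-1], 4, L), "length")
})

test_that("pattern matching recovers permutations and the optimal assignment", {
  set.seed(26)
  K <- 4; L <- 6; Np <- 2
  C <- matrix(rnorm(K * Np * L), K)
  mkModel <- function(cen) new("PatternModel", centroids = cen,
                               labels = rep(seq_len(nrow(cen)), 3),
                               markNames = paste0("m", 1:Np), L = as.integer(L),
                               seed = 1L, patternOrder = seq_len(nrow(cen)),
                               totWithinSS = 0)
  m1 <- mkModel(C)
  # self-match: identity with scores 1
  self <- matchPatterns(m1, m1)
  expect_equal(self$pattern2, self$pattern1)
  expect_true(all(abs(self$modifiedPCC - 1) < 1e-12))
  # permuted clusters are recovered
  perm <- c(3, 1, 4, 2)
  m2 <- mkModel(C[perm, ])
  got <- matchPatterns(m1, m2)
  expect_equal(got$pattern2[order(got$pattern1)], order(perm))
  # greedy equals exhaustive assignment on this instance
  opt <- matchPatterns(m1, m2, method = "optimal")
  expect_equal(got, opt, ignore_attr = TRUE)
  # K mismatch: pair min(K), report unmatched
  m3 <- mkModel(C[1:3, ])
  res <- matchPatterns(m1, m3)
  expect_equal(nrow(res), 3)
  expect_length(attr(res, "unmatched"), 1)
})

test_that("expression ranking orders clusters by median with tie rules", {
  mkModel <- function(labels, K) new("PatternModel",
    centroids = matrix(0, K, 10), labels = as.integer(labels),
    markNames = "m", L = 10L, seed = 1L, patternOrder = seq_len(K),
    totWithinSS = 0)
  m <- mkModel(c(1, 1, 2, 2), 2)
  genes <- paste0("g", 1:4)
  r <- rankByExpression(m, setNames(c(2, 2, 10, 10), genes), genes)
  expect_equal(r@patternOrder, c(2L, 1L))
  expect_equal(cpLabels(r), c(2L, 2L, 1L, 1L))
  # tied medians broken by mean, then original label
  m2 <- mkModel(c(1, 1, 1, 2, 2, 2), 2)
  g2 <- paste0("g", 1:6)
  r2 <- rankByExpression(m2, setNames(c(0, 5, 20, 4, 5, 6), g2), g2)
  expect_equal(r2@patternOrder, c(1L, 2L))  # medians tie at 5, mean 8.33 vs 5
  # cluster without expression ranks last with a warning
  m3 <- mkModel(c(1, 1, 2, 2), 2)
  expect_warning(r3 <- rankByExpression(m3, setNames(c(1, 1), c("g1", "g2")),
                                        c("g1", "g2", "gX", "gY")),
                 "ranked last")
  expect_equal(r3@patternOrder, c(1L, 2L))
})

test_that("planted promoter classes are recovered and ranked by expression", {
  sim <- simulateStack(synthConfig(nPromotersPerClass = 50L), seed = 6)
  X <- concatenateProfiles(sim$stack, c("mark01", "mark04", "mark07", "mark10"))
  m <- fitPatterns(X, 8, seed = 6)
  expect_gte(labelAgreement(sim$classes, m@labels), 0.95)
  r <- rankByExpression(m, sim$expression, sim$geneIds)
  # CP order should follow the planted activity ladder: the cluster shown
  # as CP1 must be dominated by true class 1, CP8 by class 8
  cp <- cpLabels(r)
  top <- as.integer(names(which.max(table(sim$classes[cp == 1]))))
  bottom <- as.integer(names(which.max(table(sim$classes[cp == 8]))))
  expect_equal(top, 1L)
  expect_equal(bottom, 8L)
})

test_that("cluster signal aggregation averages bin-wise", {
  sig <- matrix(c(1, 2, 3, 4,
                  5, 6, 7, 8,
                  9, 10, 11, 12), 3, 4, byrow = TRUE)
  out <- aggregateClusterSignal(c(1L, 1L, 2L), sig)
  expect_equal(unname(out[1, ]), c(3, 4, 5, 6))
  expect_equal(unname(out[2, ]), c(9, 10, 11, 12))
  # all in one cluster: column means; one per cluster: the rows
  expect_equal(unname(aggregateClusterSignal(rep(1L, 3), sig)[1, ]),
               colMeans(sig))
  expect_equal(unname(aggregateClusterSignal(1:3, sig)), unname(sig))
  expect_warning(aggregateClusterSignal(c(1L, 1L, 3L), sig), "omitted")
})

test_that("pattern models serialize to JSON and back", {
  sim <- simulateStack(synthConfig(nPromotersPerClass = 5L), seed = 2)
  X <- concatenateProfiles(sim$stack, c("mark01", "mark04"))
  m <- fitPatterns(X, 3, seed = 3)
  path <- tempfile(fileext = ".json")
  writePatternModel(m, path)
  m2 <- readPatternModel(path)
  expect_equal(m2@centroids, unname(m@centroids))
  expect_identical(m2@labels, m@labels)
  expect_identical(m2@patternOrder, m@patternOrder)
  expect_equal(m2@L, m@L)
})
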