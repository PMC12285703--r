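# Loaded-gene selection, enrichment, FDR, developmental trajectories.

test_that("selectLoadedGenes keeps the requested fraction by |loading|", {
  m <- new("PLSModel",
           u = matrix(1 / sqrt(10), 10, 1), v = matrix(1, 1, 1), s = 1,
           covExplained = 1,
           xScores = matrix(0, 4, 1), yScores = matrix(0, 4, 1),
           xLoadings = matrix(c(0.9, 0.5, 0.3, 0.1, 0.7, -0.2, -0.6, -0.4,
                                0.2, 0.8), 10, 1),
           yLoadings = matrix(1, 1, 1), pSpin = numeric(),
           bootCI = matrix(numeric(), 0, 0),
           meta = list(xIds = letters[1:10]))
  pos <- selectLoadedGenes(m, "positive", fraction = 0.5)
  expect_setequal(pos, c("a", "j", "e", "b"))   # ceiling(0.5 * 7) = 4 largest
  expect_length(selectLoadedGenes(m, "positive", fraction = 1), 7)
  neg <- selectLoadedGenes(m, "negative", fraction = 0.5)
  expect_setequal(neg, c("g", "h"))
  expect_error(selectLoadedGenes(m, "positive", fraction = 0), "fraction")
})

test_that("selected positive genes are enriched for top planted weights", {
  atlas <- midAtlas()
  tr <- makeGroundTruth(atlas, 300, seed = 1)
  X <- simulateExpression(atlas, 300, tr, seed = 2)
  Y <- outer(tr@latentMap, tr@bandWeights) +
    matrix(rnorm(600, sd = 0.3), 100)
  m <- plsLoadings(fitPLS(X, Y), X, Y)
  pos <- selectLoadedGenes(m, "positive", fraction = 0.5)
  ids <- geneIds(X)
  kept <- match(ids, sprintf("g%05d", 1:300))
  top <- ids[tr@geneWeights[kept] >= quantile(tr@geneWeights[kept], 0.9)]
  q <- length(intersect(pos, top))
  pHyper <- phyper(q - 1, length(top), length(ids) - length(top),
                   length(pos), lower.tail = FALSE)
  expect_lt(pHyper, 0.01)
})

test_that("celltype enrichment ratios, tails and FDR behave", {
  bg <- sprintf("g%03d", 1:200)
  ann <- list(a = bg[1:30], b = bg[31:80], c = bg[81:100])
  res <- celltypeEnrichment(bg[1:30], ann, bg, nPerm = 199, seed = 1)
  expect_equal(res$ratio[res$cellType == "a"], 1)
  expect_true(all(res$ratio >= 0 & res$ratio <= 1))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$direction[res$cellType == "a"], "over")
  # ratios over disjoint sets sum to at most 1
  expect_lte(sum(res$ratio), 1)
  expect_error(celltypeEnrichment(c("zz"), ann, bg), "subset")
})

test_that("enrichment attains nominal error rates on random gene sets", {
  set.seed(2)
  bg <- sprintf("g%03d", 1:300)
  ann <- list(a = bg[1:60], b = bg[61:120], c = bg[121:180])
  hits <- replicate(120, {
    gs <- sample(bg, 50)
    res <- celltypeEnrichment(gs, ann, bg, nPerm = 99,
                              seed = sample.int(1e6, 1))
    any(res$q < 0.05)
  })
  # family-wise nominal rate after BH across 3 types stays near alpha
  expect_lt(mean(hits), 0.12)
})

test_that("bhFdr matches the step-up arithmetic oracle", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  # oracle: p_(i) * n / i with cumulative minimum from the largest rank
  n <- length(p)
  adjOracle <- rev(cummin(rev(p * n / seq_len(n))))
  expect_equal(bhFdr(p), adjOracle)
  expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhFdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("developmental scores are linear in the weights", {
  tr <- makeGroundTruth(smallAtlas(), 30, seed = 1)
  ids <- sprintf("g%05d", 1:30)
  dev <- simulateDevExpression(stages = 5, geneIds = ids, truth = tr,
                               seed = 2)
  w1 <- setNames(rnorm(30), ids)
  w2 <- setNames(rnorm(30), ids)
  s1 <- devGeneScores(dev, w1)
  s2 <- devGeneScores(dev, w2)
  s12 <- devGeneScores(dev, w1 + w2)
  expect_equal(unclass(s12), unclass(s1) + unclass(s2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(devGeneScores(dev, 0 * w1) == 0))
  single <- setNames(c(1, rep(0, 29)), ids)
  expect_equal(as.vector(devGeneScores(dev, single)[2, ]),
               as.vector(dev@values[2, , 1]))
  expect_error(devGeneScores(dev, setNames(1, "nope")), "shared")
})

test_that("stage slopes are exact OLS per region", {
  sc <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(5, 3, 1, -1))
  sl <- stageSlopes(sc)
  expect_equal(unname(sl), c(1, 0, -2))
  expect_equal(unname(stageSlopes(matrix(c(1, 2, 4), 1))),
               unname(coef(lm(c(1, 2, 4) ~ seq_len(3)))[2]))
  expect_error(stageSlopes(matrix(1:2, 1)), "stages")
  # noisy recovery of the planted slope
  tr <- makeGroundTruth(smallAtlas(), 40, seed = 1)
  ids <- sprintf("g%05d", 1:40)
  ests <- sapply(1:10, function(r) {
    dev <- simulateDevExpression(stages = 8, geneIds = ids, truth = tr,
                                 seed = 100 + r)
    mean(stageSlopes(devGeneScores(dev,
      setNames(tr@geneWeights, ids)))[-12])
  })
  expect_lt(abs(mean(ests) - 0.5), 0.2)
})

test_that("spin-nulled slope test separates planted from null regions", {
  atlas <- midAtlas()
  spins <- midSpins()
  tr <- makeGroundTruth(atlas, 200, seed = 4)
  X <- simulateExpression(atlas, 200, tr, seed = 5)
  Y <- outer(tr@latentMap, tr@bandWeights) +
    matrix(rnorm(600, sd = 0.3), 100)
  ids <- geneIds(X)
  kept <- match(ids, sprintf("g%05d", 1:200))
  trK <- new("GroundTruth", h2 = tr@h2, c2 = tr@c2,
             sessionNoiseSd = tr@sessionNoiseSd, latentMap = tr@latentMap,
             geneWeights = tr@geneWeights[kept],
             bandWeights = tr@bandWeights,
             enrichedCelltype = tr@enrichedCelltype, devSlope = tr@devSlope)
  dev <- simulateDevExpression(stages = 8, geneIds = ids, truth = trK,
                               seed = 6)
  out <- slopePermutationTest(X, Y, dev, spins)
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_gt(sum(out$q[out$region != "hippocampus"] < 0.05), 8)
  expect_gt(out$q[out$region == "hippocampus"], 0.05)
})

test_that("the planted-enrichment chain beats a shuffled-weight chain", {
  atlas <- midAtlas()
  set.seed(7)
  wins <- sapply(1:5, function(r) {
    tr <- makeGroundTruth(atlas, 400, seed = r)
    X <- simulateExpression(atlas, 400, tr, seed = 10 + r)
    Y <- outer(tr@latentMap, tr@bandWeights) +
      matrix(rnorm(600, sd = 0.3), 100)
    m <- plsLoadings(fitPLS(X, Y), X, Y)
    ids <- geneIds(X)
    kept <- match(ids, sprintf("g%05d", 1:400))
    trK <- new("GroundTruth", h2 = tr@h2, c2 = tr@c2,
               sessionNoiseSd = tr@sessionNoiseSd, latentMap = tr@latentMap,
               geneWeights = tr@geneWeights[kept],
               bandWeights = tr@bandWeights,
               enrichedCelltype = tr@enrichedCelltype,
               devSlope = tr@devSlope)
    ann <- simulateCelltypeSets(ids, 7, trK, seed = 20 + r)
    pos <- selectLoadedGenes(m, "positive", fraction = 0.5)
    qReal <- celltypeEnrichment(pos, ann, ids, nPerm = 199,
                                seed = 30 + r)
    qReal <- qReal$q[qReal$cellType == trK@enrichedCelltype]
    mSh <- m
    mSh@xLoadings <- m@xLoadings[sample(nrow(m@xLoadings)), , drop = FALSE]
    posSh <- selectLoadedGenes(mSh, "positive", fraction = 0.5)
    qSh <- celltypeEnrichment(posSh, ann, ids, nPerm = 199, seed = 30 + r)
    qSh <- qSh$q[qSh$cellType == trK@enrichedCelltype]
    qReal < qSh | (qReal < 0.05 & qSh >= 0.05)
  })
  expect_gte(sum(wins), 4)
})
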