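# ICC, cross-twin correlations, Falconer maps and robustness checks.

test_that("iccOneway equals the explicit ANOVA sums-of-squares oracle", {
  expect_equal(iccOneway(rbind(c(1, 1), c(2, 2), c(3, 3))), 1)
  iccOracle <- function(x) {
    n <- nrow(x); k <- ncol(x)
    gm <- mean(x)
    ssb <- k * sum((rowMeans(x) - gm)^2)
    ssw <- sum(sweep(x, 1, rowMeans(x))^2)
    msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  }
  set.seed(3)
  for (i in 1:100) {
    x <- matrix(sample(0:9, 12, replace = TRUE) + rnorm(12, sd = 0.01),
                4, 3)
    expect_equal(iccOneway(x), iccOracle(x), tolerance = 1e-10)
  }
  set.seed(4)
  nullIcc <- replicate(1000, iccOneway(matrix(rnorm(150), 50, 3)))
  expect_lt(abs(mean(nullIcc)), 0.02)
  expect_warning(v <- iccOneway(matrix(2, 3, 3)), "undefined")
  expect_true(is.na(v))
  expect_error(iccOneway(matrix(1:3, 3, 1)), "replicates")
})

test_that("saliency map averages twin-pruned subsamples consistently", {
  expect_equal(formals(saliencyMap)$nSubsamples, 100)
  atlas <- smallAtlas()
  des <- makeCohort(4, 4, 6)
  tr <- makeGroundTruth(atlas, 1, seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 5,
                        freq = coarseFreq())
  icc <- saliencyMap(p, des, nSubsamples = 20, seed = 6)
  expect_equal(dim(icc$values), c(20, 6))
  expect_true(all(icc$values <= 1))
  expect_gt(cor(as.vector(icc$values), as.vector(icc$subsampleMean)), 0.95)
  # twin-free cohort: subsample mean equals the full map exactly
  desU <- makeCohort(0, 0, 10)
  pU <- simulateProfiles(desU, atlas, truth = tr, seed = 5,
                         freq = coarseFreq())
  iccU <- saliencyMap(pU, desU, nSubsamples = 5, seed = 6)
  expect_identical(iccU$values, iccU$subsampleMean)
})

test_that("cross-twin correlation is symmetric and hits its exact limits", {
  atlas <- smallAtlas()
  des <- makeCohort(4, 4, 0)
  tr1 <- makeGroundTruth(atlas, 1, h2 = 1, c2 = 0, sessionNoiseSd = 0,
                         seed = 1)
  p1 <- simulateProfiles(des, atlas, truth = tr1, seed = 2,
                         freq = coarseFreq())
  expect_equal(crossTwinCorrelation(p1, des, "MZ", "alpha", 2), 1,
               tolerance = 1e-10)
  # double-entry symmetry: swapping twin order leaves r unchanged
  v <- profileValues(p1)
  swapped <- v
  mz1 <- which(pairIds(des) == "MZ01")
  swapped[mz1, , , ] <- v[rev(mz1), , , ]
  pSw <- new("SpectralProfileSet", values = swapped, freq = freqGrid(p1),
             subjectIds = subjectIds(p1), sessionIds = sessionIds(p1),
             meta = list())
  trM <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  pM <- simulateProfiles(des, atlas, truth = trM, seed = 3,
                         freq = coarseFreq())
  vM <- profileValues(pM); vSw <- vM
  vSw[mz1, , , ] <- vM[rev(mz1), , , ]
  pMSw <- new("SpectralProfileSet", values = vSw, freq = freqGrid(pM),
              subjectIds = subjectIds(pM), sessionIds = sessionIds(pM),
              meta = list())
  expect_equal(crossTwinCorrelation(pM, des, "MZ", "beta", 4),
               crossTwinCorrelation(pMSw, des, "MZ", "beta", 4),
               tolerance = 1e-12)
  # independent co-twins: r near zero at 100 pairs
  desBig <- makeCohort(100, 0, 0)
  tr0 <- makeGroundTruth(atlas, 1, h2 = 0, c2 = 0, seed = 1)
  p0 <- simulateProfiles(desBig, atlas, truth = tr0, seed = 4,
                         freq = coarseFreq())
  expect_lt(abs(crossTwinCorrelation(p0, desBig, "MZ", "alpha", 2)), 0.1)
  expect_error(crossTwinCorrelation(p1, makeCohort(1, 1, 0), "MZ"), ">= 2")
})

test_that("double-entered pooled correlation matches a direct oracle", {
  # the sufficient-statistic path must equal an explicit double-entry build
  atlas <- smallAtlas()
  des <- makeCohort(5, 0, 0)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 8,
                        freq = coarseFreq())
  arr <- neuroprint:::bandMeanArray(p, defaultBands())
  pm <- neuroprint:::pairIndexMatrix(des, "MZ")
  cell <- 17L
  xs <- c(); ys <- c()
  for (k in seq_len(ncol(pm))) {
    a <- arr[pm[1, k], , cell]; b <- arr[pm[2, k], , cell]
    for (i in seq_along(a)) for (j in seq_along(b)) {
      xs <- c(xs, a[i], b[j]); ys <- c(ys, b[j], a[i])
    }
  }
  st <- neuroprint:::crossTwinStats(arr, pm)
  rFast <- neuroprint:::crossTwinRFromStats(st, seq_len(ncol(pm)))[cell]
  expect_equal(rFast, cor(xs, ys), tolerance = 1e-12)
})

test_that("falconerH2 computes and clips the twin estimate", {
  expect_equal(falconerH2(0.8, 0.4)$h2, 0.8)
  expect_equal(falconerH2(0.5, 0.5)$h2, 0)
  hi <- falconerH2(0.9, 0.2)
  expect_equal(hi$raw, 1.4)
  expect_equal(hi$h2, 1)
  lo <- falconerH2(0.1, 0.4)
  expect_equal(lo$raw, -0.6)
  expect_equal(lo$h2, 0)
  expect_error(falconerH2(1.2, 0), "\\[-1, 1\\]")
})

test_that("heritability map recovers planted h2 with calibrated permutations", {
  atlas <- makeAtlas(8, seed = 2)
  des <- makeCohort(60, 60, 0)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 9,
                        freq = coarseFreq())
  hm <- heritabilityMap(p, des, nPerm = 100, seed = 10)
  expect_lt(abs(mean(hm$h2Raw) - 0.6), 0.15)
  expect_true(all(hm$h2 >= 0 & hm$h2 <= 1))
  expect_equal(as.vector(hm$h2), pmin(1, pmax(0, as.vector(hm$h2Raw))))
  expect_true(all(hm$pPerm > 0 & hm$pPerm <= 1))
  # null data: permutation distribution centred at zero, p roughly uniform
  tr0 <- makeGroundTruth(atlas, 1, h2 = 0, c2 = 0.2, seed = 1)
  ps <- c()
  for (r in 1:3) {
    p0 <- simulateProfiles(des, atlas, truth = tr0, seed = 20 + r,
                           freq = coarseFreq())
    hm0 <- heritabilityMap(p0, des, nPerm = 99, seed = r)
    ps <- c(ps, as.vector(hm0$pPerm))
  }
  # not anti-conservative: the empirical CDF of null p-values does not sit
  # significantly above the uniform CDF
  expect_gt(suppressWarnings(ks.test(ps, "punif",
                                     alternative = "greater")$p.value), 0.01)
  expect_error(heritabilityMap(p, makeCohort(1, 1, 10)), ">= 2 MZ")
})

test_that("heritability is robust to MZ subsampling and the estimator choice", {
  atlas <- smallAtlas()
  des <- makeCohort(12, 8, 0)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 11,
                        freq = coarseFreq())
  rob <- heritabilityRobustness(p, des, seed = 12)
  expect_gt(rob$subsampleCor, 0.8)
  expect_gt(rob$estimatorCor, 0.9)
  # equal pair counts: subsampling is the identity
  desEq <- makeCohort(8, 8, 0)
  pEq <- simulateProfiles(desEq, atlas, truth = tr, seed = 13,
                          freq = coarseFreq())
  robEq <- heritabilityRobustness(pEq, desEq, seed = 14)
  expect_equal(robEq$subsampleCor, 1)
})

test_that("ICC saliency and heritability maps are spatially coupled", {
  # the planted amplitude gradient drives both within-subject stability and
  # the attenuation of cross-twin correlations
  atlas <- smallAtlas()
  des <- makeCohort(40, 40, 0)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.7, c2 = 0.1, sessionNoiseSd = 1,
                        seed = 1)
  cors <- sapply(1:3, function(r) {
    p <- simulateProfiles(des, atlas, truth = tr, seed = 30 + r,
                          freq = coarseFreq())
    icc <- saliencyMap(p, des, nSubsamples = 10, seed = r)
    hm <- heritabilityMap(p, des, nPerm = 2, seed = r)
    cor(icc$subsampleMean[, 3], hm$h2Raw[, 3])   # alpha band
  })
  expect_gt(mean(cors), 0)
})
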