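# Differentiation, twin matching, chance controls and bootstrap intervals.

test_that("similarityMatrix matches a hand-computed Pearson oracle", {
  a <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(0, 0, 1, 1))
  b <- rbind(c(4, 3, 2, 1), c(1, 3, 2, 4), c(1, 2, 2, 1))
  sim <- similarityMatrix(a, b)
  oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(sim[i, j], oracle(a[i, ], b[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(similarityMatrix(a, a)), rep(1, 3))
  # zero-variance rows flagged
  az <- a; az[2, ] <- 7
  simz <- similarityMatrix(az, b)
  expect_true(all(is.na(simz[2, ])))
  expect_equal(attr(simz, "undefined")$a, 2L)
  set.seed(1)
  g <- matrix(rnorm(10 * 100), 10)
  offd <- similarityMatrix(g, matrix(rnorm(10 * 100), 10))
  expect_lt(max(abs(offd)), 0.5)
  expect_error(similarityMatrix(a, b[, 1:3]), "differ")
})

test_that("differentiation accuracy equals a brute-force argmax oracle", {
  # tiny constructed set: 3 subjects x 2 sessions x 2 parcels x 4 bins
  vals <- array(0, c(3, 2, 2, 4))
  set.seed(5)
  vals[] <- abs(rnorm(length(vals))) + 0.5
  prof <- new("SpectralProfileSet", values = vals,
              freq = c(2, 4, 8, 16), subjectIds = c("a", "b", "c"),
              sessionIds = c("s1", "s2"), meta = list())
  res <- differentiationAccuracy(prof, band = "broadband",
                                 bands = bandScheme("bb", 2, 16))
  oracleHits <- c()
  for (pr in 1:2) for (te in 1:2) {
    if (pr == te) next
    for (i in 1:3) {
      ri <- sapply(1:3, function(j) {
        cor(as.vector(vals[i, pr, , ]), as.vector(vals[j, te, , ]))
      })
      oracleHits <- c(oracleHits, which.max(ri) == i &&
                        sum(ri == max(ri)) == 1)
    }
  }
  expect_equal(res$accuracy, mean(oracleHits))
  expect_equal(res$accuracy, mean(res$perPairAccuracy))
})

test_that("differentiation hits ceiling without noise and floor when sessions are independent", {
  atlas <- smallAtlas()
  des <- makeCohort(0, 0, 30)
  tr0 <- makeGroundTruth(atlas, 1, sessionNoiseSd = 0, seed = 1)
  p0 <- simulateProfiles(des, atlas, truth = tr0, seed = 2,
                         freq = coarseFreq())
  expect_equal(differentiationAccuracy(p0)$accuracy, 1.0)
  # fully session-independent profiles: chance floor 1/N. The 180 trials of
  # one cohort are positively correlated, so average over replicates and
  # compare against the single-run binomial band.
  acc <- mean(sapply(1:4, function(r) {
    ind <- simulateNoiseProfiles(des, atlas, seed = 2 + r,
                                 mixInstability = 1, freq = coarseFreq())
    differentiationAccuracy(ind)$accuracy
  }))
  n <- 30 * 6   # subjects x ordered session pairs
  band <- 1 / 30 + c(-1, 1) * 1.96 * sqrt((1 / 30) * (29 / 30) / n)
  expect_gt(acc, band[1])
  expect_lt(acc, band[2])
})

test_that("accuracy is invariant to feature-wise affine rescaling", {
  prof <- smallProfiles()
  base <- differentiationAccuracy(prof)
  v <- profileValues(prof)
  scale <- runif(dim(v)[4], 0.5, 2)
  shift <- runif(dim(v)[4], 0, 5)
  v2 <- sweep(sweep(v, 4, scale, "*"), 4, shift, "+")
  prof2 <- new("SpectralProfileSet", values = v2, freq = freqGrid(prof),
               subjectIds = subjectIds(prof), sessionIds = sessionIds(prof),
               meta = list())
  expect_equal(differentiationAccuracy(prof2)$accuracy, base$accuracy)
})

test_that("rising session noise never raises expected accuracy", {
  atlas <- smallAtlas()
  des <- makeCohort(0, 0, 20)
  grid <- c(0.3, 1, 3, 10)
  accs <- sapply(grid, function(sn) {
    mean(sapply(1:3, function(r) {
      tr <- makeGroundTruth(atlas, 1, sessionNoiseSd = sn, seed = 1)
      p <- simulateProfiles(des, atlas, truth = tr, seed = 50 + r,
                            freq = coarseFreq())
      differentiationAccuracy(p)$accuracy
    }))
  })
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("twin matching is exact for identical co-twins and near chance for independents", {
  atlas <- smallAtlas()
  des <- makeCohort(3, 0, 10)
  tr1 <- makeGroundTruth(atlas, 1, h2 = 1, c2 = 0, sessionNoiseSd = 0,
                         seed = 1)
  p1 <- simulateProfiles(des, atlas, truth = tr1, seed = 2,
                         freq = coarseFreq())
  expect_equal(twinMatchingAccuracy(p1, des, "MZ")$accuracy, 1.0)
  # independent profiles: co-twin wins ~ 1/(N-1)
  desI <- makeCohort(8, 0, 14)
  accs <- sapply(1:4, function(r) {
    pI <- simulateNoiseProfiles(desI, atlas, seed = 10 + r,
                                mixInstability = 1, freq = coarseFreq())
    twinMatchingAccuracy(pI, desI, "MZ")$accuracy
  })
  n <- 30
  expect_lt(abs(mean(accs) - 1 / (n - 1)), 0.05)
  expect_error(twinMatchingAccuracy(p1, makeCohort(0, 0, 36), "MZ"),
               "no pairs")
})

test_that("MZ matching beats DZ matching on planted twin structure", {
  atlas <- smallAtlas()
  des <- makeCohort(8, 8, 10)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.5, c2 = 0.2, seed = 1)
  wins <- sapply(1:6, function(r) {
    p <- simulateProfiles(des, atlas, truth = tr, seed = 60 + r,
                          freq = coarseFreq())
    twinMatchingAccuracy(p, des, "MZ")$accuracy >
      twinMatchingAccuracy(p, des, "DZ")$accuracy
  })
  expect_gte(sum(wins), 5)
})

test_that("random pairing of unrelated subjects stays near chance", {
  atlas <- smallAtlas()
  des <- makeCohort(2, 2, 31)   # odd unrelated count: one left out
  tr <- makeGroundTruth(atlas, 1, seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 4,
                        freq = coarseFreq())
  expect_equal(formals(randomPairMatching)$nIter, 300)
  r1 <- randomPairMatching(p, des, nIter = 30, seed = 9)
  r2 <- randomPairMatching(p, des, nIter = 30, seed = 9)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_equal(r1$leftOutPerIter, 1)
  expect_lt(r1$accuracy, 0.05)
  expect_error(randomPairMatching(p, makeCohort(10, 10, 2), seed = 1),
               "unrelated")
})

test_that("bootstrap CI is a valid percentile interval", {
  prof <- smallProfiles()
  des <- smallCohort()
  const <- bootstrapAccuracyCI(prof, des, function(p, d) 0.7,
                               nBoot = 20, seed = 1)
  expect_equal(const$ci, c(0.7, 0.7))
  expect_equal(formals(bootstrapAccuracyCI)$nBoot, 1000)
  ci <- bootstrapAccuracyCI(prof, des,
                            function(p, d) differentiationAccuracy(p)$accuracy,
                            nBoot = 25, seed = 2)
  expect_true(ci$ci[1] <= ci$ci[2])
  expect_true(all(ci$ci >= 0 & ci$ci <= 1))
})

test_that("self / twin / other similarity distributions are ordered", {
  atlas <- smallAtlas()
  des <- makeCohort(6, 6, 6)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  means <- sapply(1:5, function(r) {
    p <- simulateProfiles(des, atlas, truth = tr, seed = 70 + r,
                          freq = coarseFreq())
    s <- selfOtherDistributions(p, des)
    c(mean(s$self), mean(s$twinMZ), mean(s$other), length(s$self))
  })
  expect_gt(mean(means[1, ]), mean(means[2, ]))   # self > MZ twin
  expect_gt(mean(means[2, ]), mean(means[3, ]))   # MZ twin > other
  expect_equal(means[4, 1], nSubjects(des) * 6)   # subjects x session pairs
  # zero noise: self-similarity exactly 1
  tr0 <- makeGroundTruth(atlas, 1, sessionNoiseSd = 0, seed = 1)
  p0 <- simulateProfiles(des, atlas, truth = tr0, seed = 2,
                         freq = coarseFreq())
  expect_true(all(abs(selfOtherDistributions(p0, des)$self - 1) < 1e-12))
})

test_that("mock noise profiles underperform planted profiles in every band", {
  atlas <- smallAtlas()
  des <- makeCohort(0, 0, 25)
  tr <- makeGroundTruth(atlas, 1, seed = 1)
  planted <- simulateProfiles(des, atlas, truth = tr, seed = 3)
  mock <- simulateNoiseProfiles(des, atlas, seed = 3)
  for (b in c("broadband", bandNames(defaultBands()))) {
    expect_lt(differentiationAccuracy(mock, b)$accuracy,
              differentiationAccuracy(planted, b)$accuracy)
  }
})
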