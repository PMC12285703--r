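# Generators: construction invariants, determinism, and planted structure.

test_that("makeAtlas builds a valid, deterministic bilateral atlas", {
  a <- makeAtlas(100, seed = 1)
  expect_equal(nParcels(a), 100)
  expect_equal(sum(hemispheres(a) == "L"), 50)
  expect_equal(sum(hemispheres(a) == "R"), 50)
  expect_true(all(abs(sqrt(rowSums(centroids(a)^2)) - 1) < 1e-9))
  expect_identical(centroids(a), centroids(makeAtlas(100, seed = 1)))
  expect_false(identical(centroids(a), centroids(makeAtlas(100, seed = 2))))
  expect_error(makeAtlas(101, seed = 1), "even")
  expect_error(makeAtlas(2, seed = 1), "nParcels")
})

test_that("makeCohort reproduces the reference design and pair invariants", {
  d <- makeCohort(17, 11, 33)
  expect_equal(nSubjects(d), 89)
  expect_equal(sum(zygosity(d) == "MZ"), 34)
  expect_equal(sum(zygosity(d) == "DZ"), 22)
  d0 <- makeCohort(0, 0, 5)
  expect_true(all(is.na(pairIds(d0))))
  d2 <- makeCohort(1, 1, 0)
  expect_equal(nSubjects(d2), 4)
  tab <- table(pairIds(d2))
  expect_true(all(tab == 2))
  expect_error(makeCohort(0, 0, 1), "at least 2")
})

test_that("simulated profiles honour the twin model in the exact limits", {
  atlas <- smallAtlas()
  des <- makeCohort(2, 2, 1)
  trMz <- makeGroundTruth(atlas, 1, h2 = 1, c2 = 0, sessionNoiseSd = 0,
                          seed = 1)
  p <- simulateProfiles(des, atlas, truth = trMz, seed = 3,
                        freq = coarseFreq())
  v <- profileValues(p)
  mzPair <- which(pairIds(des) == "MZ01")
  expect_equal(v[mzPair[1], , , ], v[mzPair[2], , , ])
  dzPair <- which(pairIds(des) == "DZ01")
  expect_false(isTRUE(all.equal(v[dzPair[1], , , ], v[dzPair[2], , , ])))
  expect_true(all(v >= 0))
  # determinism
  p2 <- simulateProfiles(des, atlas, truth = trMz, seed = 3,
                         freq = coarseFreq())
  expect_identical(profileValues(p), profileValues(p2))
  expect_error(
    simulateProfiles(des, atlas,
                     truth = new("GroundTruth", h2 = 0.8, c2 = 0.1,
                                 sessionNoiseSd = 0, latentMap = rep(0, 20),
                                 geneWeights = 0, bandWeights = rep(0, 6),
                                 enrichedCelltype = "x", devSlope = 0),
                     seed = 1, nSessions = 1),
    "nSessions")
})

test_that("cross-twin correlations follow Falconer algebra on average", {
  atlas <- makeAtlas(8, seed = 2)
  des <- makeCohort(100, 100, 0)
  # h2 = 0, c2 = 0: both zygosities uncorrelated
  tr0 <- makeGroundTruth(atlas, 1, h2 = 0, c2 = 0, sessionNoiseSd = 0,
                         seed = 1)
  p0 <- simulateProfiles(des, atlas, truth = tr0, seed = 11,
                         freq = coarseFreq())
  hm0 <- heritabilityMap(p0, des, nPerm = 2, seed = 1)
  expect_lt(abs(mean(hm0$rMz)), 0.1)
  expect_lt(abs(mean(hm0$rDz)), 0.1)
  # h2 = 0.6, c2 = 0.2: r_MZ = 0.8, r_DZ = 0.5 (no session noise)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.2, sessionNoiseSd = 0,
                        seed = 1)
  diffs <- vapply(1:4, function(r) {
    p <- simulateProfiles(des, atlas, truth = tr, seed = 20 + r,
                          freq = coarseFreq())
    hm <- heritabilityMap(p, des, nPerm = 2, seed = r)
    mean(hm$rMz) - mean(hm$rDz)
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.3), 0.07)
})

test_that("between-subject variance matches the planted component sum", {
  # variance accounting at zero session noise: trait variance is h2+c2+e2 = 1
  # times the squared parcel-band amplitude
  atlas <- smallAtlas()
  des <- makeCohort(0, 0, 600)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.5, c2 = 0.3, sessionNoiseSd = 0,
                        seed = 1)
  p <- simulateProfiles(des, atlas, truth = tr, seed = 5, nSessions = 2,
                        freq = coarseFreq())
  v <- profileValues(p)[, 1, , ]
  # pick a high-frequency bin outside all bands: amplitude exactly 1
  f <- length(freqGrid(p))
  emp <- mean(apply(v[, , f], 2, var))
  expect_lt(abs(emp - 1), 0.05)
})

test_that("Falconer identity holds on simulated data across replicates", {
  atlas <- makeAtlas(6, seed = 3)
  des <- makeCohort(200, 200, 0)
  tr <- makeGroundTruth(atlas, 1, h2 = 0.6, c2 = 0.1, seed = 1)
  err <- vapply(1:6, function(r) {
    p <- simulateProfiles(des, atlas, truth = tr, seed = 40 + r,
                          freq = coarseFreq())
    hm <- heritabilityMap(p, des, nPerm = 2, seed = r)
    abs(mean(hm$h2Raw) - 0.6)
  }, numeric(1))
  expect_lt(mean(err), 0.1)
})

test_that("simulated expression carries the planted gradient and stability", {
  atlas <- smallAtlas()
  tr <- makeGroundTruth(atlas, 40, seed = 1)
  # zero noise: donors identical, stability 1
  e0 <- simulateExpression(atlas, 40, tr, noiseSd = 0, nDonors = 3, seed = 2)
  expect_true(all(abs(dsValues(e0) - 1) < 1e-12))
  # zero gene weights, no nuisance: no gene-latent correlation
  trZ <- new("GroundTruth", h2 = 0.6, c2 = 0.1, sessionNoiseSd = 0.3,
             latentMap = tr@latentMap, geneWeights = rep(0, 40),
             bandWeights = tr@bandWeights, enrichedCelltype = "x",
             devSlope = 0.5)
  eZ <- simulateExpression(atlas, 40, trZ, nNuisance = 0, seed = 3)
  cors <- cor(exprValues(eZ), tr@latentMap)
  expect_lt(abs(mean(cors)), 0.12)
  # vanishing autocorrelation length: no neighbour correlation
  eI <- simulateExpression(atlas, 200, trZ200 <- new("GroundTruth",
    h2 = 0.6, c2 = 0.1, sessionNoiseSd = 0.3, latentMap = tr@latentMap,
    geneWeights = rep(0, 200), bandWeights = tr@bandWeights,
    enrichedCelltype = "x", devSlope = 0.5),
    autocorrLength = 1e-4, nNuisance = 0, seed = 4)
  cen <- centroids(atlas)
  D <- as.matrix(dist(cen)); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  m <- exprValues(eI)
  nbCor <- mean(vapply(seq_len(ncol(m)), function(j) cor(m[, j], m[nn, j]),
                       numeric(1)))
  expect_lt(abs(nbCor), 0.1)
  expect_error(simulateExpression(atlas, 40, tr, autocorrLength = 0),
               "positive")
})

test_that("term maps recover the planted sign split", {
  atlas <- smallAtlas()
  tr <- makeGroundTruth(atlas, 4, seed = 1)
  t0 <- simulateTermMaps(atlas, 4, tr, noiseSd = 0, seed = 2)
  cors <- as.vector(cor(t0, tr@latentMap))
  expect_equal(cors, attr(t0, "plantedSign") * 1, tolerance = 1e-12)
  tn <- simulateTermMaps(atlas, 6, tr, seed = 2)
  expect_identical(tn, simulateTermMaps(atlas, 6, tr, seed = 2))
  expect_equal(sign(as.vector(cor(tn, tr@latentMap))),
               attr(tn, "plantedSign"))
})

test_that("cell-type sets are disjoint with planted top-decile enrichment", {
  tr <- makeGroundTruth(smallAtlas(), 600, seed = 1)
  ids <- sprintf("g%05d", 1:600)
  ann <- simulateCelltypeSets(ids, 7, tr, seed = 2)
  expect_length(ann, 7)
  expect_equal(anyDuplicated(unlist(ann)), 0)
  expect_true(tr@enrichedCelltype %in% names(ann))
  top <- ids[tr@geneWeights >= quantile(tr@geneWeights, 0.9)]
  inEnr <- mean(ann[[tr@enrichedCelltype]] %in% top)
  others <- mean(unlist(ann[names(ann) != tr@enrichedCelltype]) %in% top)
  # hypergeometric oracle: background rate is 10%; planted rate ~2x that
  n <- length(ann[[tr@enrichedCelltype]])
  pOracle <- phyper(sum(ann[[tr@enrichedCelltype]] %in% top) - 1,
                    length(top), 600 - length(top), n, lower.tail = FALSE)
  expect_lt(pOracle, 0.05)
  expect_gt(inEnr, others)
  ann2 <- simulateCelltypeSets(ids, 7, tr, seed = 3)
  expect_false(identical(ann, ann2))
  expect_error(simulateCelltypeSets(ids[1:20], 7, tr2 <- makeGroundTruth(
    smallAtlas(), 20, seed = 1), setSize = 5), "exceed")
})

test_that("developmental expression plants linear slopes except one region", {
  tr <- makeGroundTruth(smallAtlas(), 50, seed = 1)
  ids <- sprintf("g%05d", 1:50)
  dev0 <- simulateDevExpression(stages = 6, geneIds = ids, truth = tr,
                                scoreNoiseSd = 0, seed = 2)
  expect_equal(dim(dev0@values), c(12, 6, 50))
  sc <- devGeneScores(dev0, setNames(tr@geneWeights, ids))
  sl <- stageSlopes(sc)
  expect_equal(unname(sl["DFC"]), tr@devSlope, tolerance = 1e-10)
  expect_equal(unname(sl["hippocampus"]), 0, tolerance = 1e-10)
  devN <- simulateDevExpression(stages = 6, geneIds = ids, truth = tr,
                                seed = 2)
  slN <- stageSlopes(devGeneScores(devN, setNames(tr@geneWeights, ids)))
  expect_lt(abs(slN["hippocampus"]), 0.2)
  expect_error(simulateDevExpression(stages = 2, geneIds = ids, truth = tr),
               "stages")
})

test_that("mock noise profiles are deterministic with weak self-structure", {
  atlas <- smallAtlas()
  des <- makeCohort(0, 0, 20)
  m1 <- simulateNoiseProfiles(des, atlas, seed = 4, freq = coarseFreq())
  m2 <- simulateNoiseProfiles(des, atlas, seed = 4, freq = coarseFreq())
  expect_identical(profileValues(m1), profileValues(m2))
  expect_true(all(profileValues(m1) >= 0))
  tr <- makeGroundTruth(atlas, 1, seed = 1)
  planted <- simulateProfiles(des, atlas, truth = tr, seed = 4,
                              freq = coarseFreq())
  accMock <- differentiationAccuracy(m1)$accuracy
  accPlanted <- differentiationAccuracy(planted)$accuracy
  expect_lt(accMock, accPlanted)
})
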