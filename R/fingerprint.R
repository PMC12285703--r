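# Individual differentiation and twin matching from spectral profiles.
# All similarity is Pearson correlation of the concatenated parcel x bin
# feature vector; argmax ties count as failures (conservative).

# Per-session subjects x features matrices for a band selection.
# band = "broadband" (1 Hz to the top of the grid) or a band name.
fingerprintFeatures <- function(profiles, band = "broadband",
                                bands = defaultBands()) {
  freq <- freqGrid(profiles)
  vals <- profileValues(profiles)
  if (identical(band, "broadband")) {
    lo <- max(1, min(freq)); hi <- max(freq)
  } else {
    i <- match(band, bands@name)
    if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
    lo <- bands@lo[i]; hi <- bands@hi[i]
  }
  sel <- bandBinIndices(freq, lo, hi)
  d <- dim(vals)
  lapply(seq_len(d[2]), function(t) {
    matrix(vals[, t, , sel, drop = FALSE], d[1], d[3] * length(sel))
  })
}

#' Between-cohort profile similarity matrix
#'
#' Entry (i, j) is the Pearson correlation between subject i's feature
#' vector from one session and subject j's from another.
#'
#' @param featuresA,featuresB subjects x features numeric matrices with the
#'   same feature dimension (>= 2 features).
#'
#' @return subjects x subjects correlation matrix. Rows/columns arising from
#'   zero-variance feature vectors are \code{NA} and flagged via the
#'   \code{"undefined"} attribute.
#' @examples
#' a <- matrix(rnorm(20), 4)
#' similarityMatrix(a, a)
#' @export
similarityMatrix <- function(featuresA, featuresB) {
  if (ncol(featuresA) != ncol(featuresB)) {
    stop("feature dimensions differ", call. = FALSE)
  }
  if (ncol(featuresA) < 2L) stop("need at least 2 features", call. = FALSE)
  sdA <- apply(featuresA, 1L, stats::sd)
  sdB <- apply(featuresB, 1L, stats::sd)
  out <- suppressWarnings(stats::cor(t(featuresA), t(featuresB)))
  out[sdA == 0, ] <- NA_real_
  out[, sdB == 0] <- NA_real_
  und <- list(a = which(sdA == 0), b = which(sdB == 0))
  if (length(und$a) || length(und$b)) attr(out, "undefined") <- und
  out
}

# Similarity matrices for every ordered session pair.
sessionPairSims <- function(profiles, band, bands) {
  feats <- fingerprintFeatures(profiles, band, bands)
  nT <- length(feats)
  pairs <- expand.grid(probe = seq_len(nT), test = seq_len(nT))
  pairs <- pairs[pairs$probe != pairs$test, , drop = FALSE]
  sims <- lapply(seq_len(nrow(pairs)), function(k) {
    similarityMatrix(feats[[pairs$probe[k]]], feats[[pairs$test[k]]])
  })
  names(sims) <- sprintf("%d->%d", pairs$probe, pairs$test)
  list(sims = sims, pairs = pairs)
}

#' Individual differentiation accuracy
#'
#' A participant is correctly differentiated when, probing with their profile
#' from one session against the gallery of all participants' profiles from
#' another session (their own included), the highest correlation is attained
#' by their own profile. The reported accuracy is the mean over all ordered
#' session pairs. Exact correlation ties count as failures.
#'
#' @param profiles a [SpectralProfileSet-class] with >= 2 subjects and >= 2
#'   sessions.
#' @param band \code{"broadband"} (default) or a band name from
#'   \code{bands}; per-bin features of that band are used.
#' @param bands a [BandScheme-class] (default [defaultBands()]).
#'
#' @return List of class \code{"FingerprintResult"}: \code{accuracy},
#'   \code{perPairAccuracy}, \code{perSubjectHits} (subjects x session
#'   pairs), \code{similarity} (list of matrices), \code{band}.
#' @examples
#' prof <- simulateProfiles(makeCohort(0, 0, 8), makeAtlas(10, 1), seed = 1)
#' differentiationAccuracy(prof)$accuracy
#' @export
differentiationAccuracy <- function(profiles, band = "broadband",
                                    bands = defaultBands()) {
  if (nSubjects(profiles) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (nSessions(profiles) < 2L) stop("need >= 2 sessions", call. = FALSE)
  sp <- sessionPairSims(profiles, band, bands)
  hits <- vapply(sp$sims, function(sim) {
    vapply(seq_len(nrow(sim)), function(i) {
      isTRUE(sim[i, i] > max(sim[i, -i]))
    }, logical(1))
  }, logical(nrow(sp$sims[[1]])))
  perPair <- colMeans(hits)
  structure(
    list(accuracy = mean(perPair), perPairAccuracy = perPair,
         perSubjectHits = hits, similarity = sp$sims, band = band,
         ci95 = NULL),
    class = "FingerprintResult")
}

# Twin/pseudo-pair matching given precomputed session-pair similarities.
# pairsIdx: 2 x nPairs subject-index matrix. Each member of each pair probes
# once per ordered session pair; the probe matches when their partner attains
# the strictly highest correlation among all participants except the probe.
matchFromSims <- function(sims, pairsIdx) {
  if (ncol(pairsIdx) < 1L) stop("no pairs to match", call. = FALSE)
  probes <- rbind(as.vector(pairsIdx), as.vector(pairsIdx[2:1, ]))
  hits <- matrix(NA, ncol(probes), length(sims))
  for (k in seq_along(sims)) {
    sim <- sims[[k]]
    for (q in seq_len(ncol(probes))) {
      i <- probes[1L, q]; j <- probes[2L, q]
      rivals <- setdiff(seq_len(ncol(sim)), c(i, j))
      hits[q, k] <- isTRUE(sim[i, j] > max(sim[i, rivals]))
    }
  }
  mean(hits)
}

#' Twin-pair matching accuracy
#'
#' A probe twin is matched when their co-twin's profile (from another
#' session) attains the highest correlation among all other participants
#' (the probe's own profile is excluded from the gallery). Accuracy is the
#' fraction of matched probes over both twins of every pair of the requested
#' zygosity, averaged across ordered session pairs.
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class] aligned with the profiles.
#' @param zygo \code{"MZ"} or \code{"DZ"}.
#' @param band,bands feature selection as in [differentiationAccuracy()].
#' @param perPair if \code{TRUE}, score a pair as matched only when both
#'   probes match (per-pair denominator); default \code{FALSE} (per-probe).
#'
#' @return List of class \code{"MatchResult"}: \code{zygosity},
#'   \code{accuracy}, \code{nPairs}, \code{ci95}.
#' @examples
#' des <- makeCohort(3, 3, 2)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' twinMatchingAccuracy(prof, des, "MZ")$accuracy
#' @export
twinMatchingAccuracy <- function(profiles, design, zygo = c("MZ", "DZ"),
                                 band = "broadband", bands = defaultBands(),
                                 perPair = FALSE) {
  zygo <- match.arg(zygo)
  pairsIdx <- pairIndexMatrix(design, zygo)
  if (ncol(pairsIdx) < 1L) {
    stop("no pairs of zygosity ", zygo, call. = FALSE)
  }
  sp <- sessionPairSims(profiles, band, bands)
  acc <- if (perPair) {
    hits <- vapply(seq_len(ncol(pairsIdx)), function(k) {
      matchFromSims(sp$sims, pairsIdx[, k, drop = FALSE]) == 1
    }, logical(1))
    mean(hits)
  } else {
    matchFromSims(sp$sims, pairsIdx)
  }
  structure(
    list(zygosity = zygo, accuracy = acc, nPairs = ncol(pairsIdx),
         ci95 = NULL),
    class = "MatchResult")
}

#' Chance-level matching of randomly paired unrelated individuals
#'
#' Randomly pairs the cohort's unrelated subjects and computes the pair
#' matching accuracy, repeated \code{nIter} times (default 300). With an odd
#' number of unrelated subjects one subject is left out per iteration
#' (recorded in the result).
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class] with >= 4 unrelated subjects.
#' @param nIter number of random pairings (default 300).
#' @param seed integer seed.
#' @param band,bands feature selection as in [differentiationAccuracy()].
#'
#' @return List of class \code{"MatchResult"}: \code{zygosity = "RANDOM"},
#'   \code{accuracy} (mean over iterations), \code{accuracies}
#'   (per-iteration), \code{nPairs}, \code{leftOutPerIter}.
#' @examples
#' des <- makeCohort(0, 0, 8)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' randomPairMatching(prof, des, nIter = 5, seed = 2)$accuracy
#' @export
randomPairMatching <- function(profiles, design, nIter = 300, seed = 1,
                               band = "broadband", bands = defaultBands()) {
  unrel <- which(zygosity(design) == "UNRELATED")
  if (length(unrel) < 4L) {
    stop("need >= 4 unrelated subjects", call. = FALSE)
  }
  sp <- sessionPairSims(profiles, band, bands)
  nPairs <- length(unrel) %/% 2L
  leftOut <- length(unrel) %% 2L
  accs <- withSeed(seed, {
    vapply(seq_len(nIter), function(it) {
      perm <- sample(unrel)
      matchFromSims(sp$sims, matrix(perm[seq_len(2L * nPairs)], 2L))
    }, numeric(1))
  })
  structure(
    list(zygosity = "RANDOM", accuracy = mean(accs), accuracies = accs,
         nPairs = nPairs, leftOutPerIter = leftOut, ci95 = NULL),
    class = "MatchResult")
}

# Subset a profile set / design to a subject-index vector; twins whose
# co-twin is dropped become UNRELATED singletons.
subsetProfiles <- function(profiles, idx) {
  new("SpectralProfileSet",
      values = profiles@values[idx, , , , drop = FALSE],
      freq = profiles@freq,
      subjectIds = profiles@subjectIds[idx],
      sessionIds = profiles@sessionIds,
      meta = profiles@meta)
}

subsetDesign <- function(design, idx) {
  pid <- design@pairId[idx]
  zyg <- design@zygosity[idx]
  orphan <- !is.na(pid) & !(pid %in% names(which(table(pid) == 2L)))
  pid[orphan] <- NA_character_
  zyg[orphan] <- "UNRELATED"
  new("CohortDesign", subjectId = design@subjectId[idx],
      pairId = pid, zygosity = zyg)
}

#' Bootstrap confidence interval for an accuracy statistic
#'
#' Recomputes a statistic over random subcohorts holding about
#' \code{frac} of the cohort (whole twin pairs are kept or dropped
#' together, so twin statistics resample pairs) and returns the percentile
#' 95\% interval from the 2.5th/97.5th percentiles of the bootstrap
#' distribution.
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class].
#' @param statistic \code{function(profiles, design) -> numeric scalar}.
#' @param frac fraction of MZ pairs, DZ pairs and unrelated subjects drawn
#'   per iteration (default 0.9).
#' @param nBoot number of bootstrap iterations (default 1000).
#' @param seed integer seed.
#'
#' @return List: \code{ci} (length-2), \code{stats} (successful iterations),
#'   \code{nSkipped} (iterations where the statistic failed on the subset).
#' @examples
#' des <- makeCohort(0, 0, 10)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' bootstrapAccuracyCI(prof, des,
#'   function(p, d) differentiationAccuracy(p)$accuracy,
#'   nBoot = 10, seed = 2)$ci
#' @export
bootstrapAccuracyCI <- function(profiles, design, statistic, frac = 0.9,
                                nBoot = 1000, seed = 1) {
  mz <- pairIndexMatrix(design, "MZ")
  dz <- pairIndexMatrix(design, "DZ")
  unrel <- which(zygosity(design) == "UNRELATED")
  withSeed(seed, {
    vals <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      keep <- c(
        if (ncol(mz)) as.vector(mz[, sample(ncol(mz), round(frac * ncol(mz))),
                                   drop = FALSE]),
        if (ncol(dz)) as.vector(dz[, sample(ncol(dz), round(frac * ncol(dz))),
                                   drop = FALSE]),
        if (length(unrel)) sample(unrel, round(frac * length(unrel)))
      )
      keep <- sort(keep)
      vals[b] <- tryCatch(
        statistic(subsetProfiles(profiles, keep), subsetDesign(design, keep)),
        error = function(e) NA_real_)
    }
    ok <- vals[!is.na(vals)]
    if (!length(ok)) stop("statistic failed on every subset", call. = FALSE)
    list(ci = unname(stats::quantile(ok, c(0.025, 0.975))), stats = ok,
         nSkipped = sum(is.na(vals)))
  })
}

#' Self-, twin- and other-similarity distributions
#'
#' Pools, over all ordered session pairs, the cross-session correlations of
#' each subject with themself (\code{self}), with their co-twin
#' (\code{twin}, split by zygosity) and with everyone else (\code{other}).
#'
#' @param profiles a [SpectralProfileSet-class] with >= 2 sessions.
#' @param design a [CohortDesign-class].
#' @param band,bands feature selection as in [differentiationAccuracy()].
#'
#' @return List of numeric vectors \code{self}, \code{twinMZ}, \code{twinDZ},
#'   \code{other}, plus a \code{summary} data.frame of means and counts.
#' @examples
#' des <- makeCohort(2, 2, 2)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' selfOtherDistributions(prof, des)$summary
#' @export
selfOtherDistributions <- function(profiles, design, band = "broadband",
                                   bands = defaultBands()) {
  if (nSessions(profiles) < 2L) stop("need >= 2 sessions", call. = FALSE)
  sp <- sessionPairSims(profiles, band, bands)
  n <- nSubjects(profiles)
  twinOf <- rep(NA_integer_, n)
  pm <- pairIndexMatrix(design)
  if (ncol(pm)) {
    twinOf[pm[1L, ]] <- pm[2L, ]
    twinOf[pm[2L, ]] <- pm[1L, ]
  }
  zyg <- zygosity(design)
  self <- c(); twinMZ <- c(); twinDZ <- c(); other <- c()
  for (sim in sp$sims) {
    self <- c(self, diag(sim))
    mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
    for (i in which(!is.na(twinOf))) {
      v <- sim[i, twinOf[i]]
      if (zyg[i] == "MZ") twinMZ <- c(twinMZ, v) else twinDZ <- c(twinDZ, v)
      mask[i, twinOf[i]] <- FALSE
    }
    other <- c(other, sim[mask])
  }
  summ <- data.frame(
    group = c("self", "twinMZ", "twinDZ", "other"),
    mean = c(mean(self), mean(twinMZ), mean(twinDZ), mean(other)),
    n = c(length(self), length(twinMZ), length(twinDZ), length(other))
  )
  list(self = self, twinMZ = twinMZ, twinDZ = twinDZ, other = other,
       summary = summ)
}

#' @export
print.FingerprintResult <- function(x, ...) {
  cat(sprintf("Differentiation accuracy (%s): %.1f%% over %d session pairs\n",
              x$band, 100 * x$accuracy, length(x$perPairAccuracy)))
  invisible(x)
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("%s matching accuracy: %.1f%% (%d pairs)\n",
              x$zygosity, 100 * x$accuracy, x$nPairs))
  invisible(x)
}
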