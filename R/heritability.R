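# ICC saliency maps, cross-twin cross-session correlations and Falconer
# twin heritability with permutation significance.

#' One-way random-effects intraclass correlation
#'
#' ICC(1) from a one-way ANOVA over subjects with k replicates:
#' \deqn{ICC = (MS_B - MS_W) / (MS_B + (k - 1) MS_W).}
#'
#' @param observations subjects x replicates numeric matrix, no missing
#'   cells, >= 2 subjects and >= 2 replicates.
#'
#' @return ICC scalar; \code{NA} (flagged via a warning) when the total
#'   variance is zero.
#' @examples
#' iccOneway(rbind(c(1, 1), c(2, 2), c(3, 3)))  # 1
#' @export
iccOneway <- function(observations) {
  x <- as.matrix(observations)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need >= 2 subjects and >= 2 replicates", call. = FALSE)
  }
  if (anyNA(x)) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  rm <- rowMeans(x)
  gm <- mean(x)
  msb <- k * sum((rm - gm)^2) / (n - 1)
  msw <- sum((x - rm)^2) / (n * (k - 1))
  if (msb + msw == 0) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  (msb - msw) / (msb + (k - 1) * msw)
}

# Vectorised ICC(1) over cells: arr has dim (subjects, replicates, cells).
iccCellwise <- function(arr) {
  n <- dim(arr)[1]; k <- dim(arr)[2]; C <- dim(arr)[3]
  subjMean <- colMeans(aperm(arr, c(2, 1, 3)))           # n x C
  grand <- colMeans(subjMean)
  msb <- k * colSums(sweep(subjMean, 2L, grand)^2) / (n - 1)
  dev <- sweep(arr, c(1, 3), subjMean)   # subject means out, per replicate
  msw <- apply(dev^2, 3L, sum) / (n * (k - 1))
  out <- (msb - msw) / (msb + (k - 1) * msw)
  out[msb + msw == 0] <- NA_real_
  out
}

# Band-mean features reshaped to (subjects, sessions, parcels * bands).
bandMeanArray <- function(profiles, bands) {
  bm <- bandFeatures(profiles, bands, "band_mean")
  d <- dim(bm)
  array(bm, c(d[1], d[2], d[3] * d[4]))
}

#' ICC saliency map with twin-aware subsampling
#'
#' Per parcel and band, the one-way ICC of band-mean power over subjects
#' (rows) and sessions (replicates): high values mark features that are
#' stable within and variable between individuals. To avoid twin-induced
#' bias the ICC is also averaged over \code{nSubsamples} random subcohorts
#' containing exactly one twin per pair (plus all unrelated subjects).
#'
#' @param profiles a [SpectralProfileSet-class] with >= 2 sessions.
#' @param design a [CohortDesign-class].
#' @param bands a [BandScheme-class] (default [defaultBands()]).
#' @param nSubsamples number of twin-pruned subsamples (default 100).
#' @param seed integer seed.
#'
#' @return List of class \code{"ICCMap"}: \code{values} (parcels x bands,
#'   full cohort), \code{subsampleMean} (same shape), \code{nSubsamples},
#'   \code{bands}.
#' @examples
#' des <- makeCohort(2, 2, 4)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' icc <- saliencyMap(prof, des, nSubsamples = 5, seed = 2)
#' dim(icc$values)
#' @export
saliencyMap <- function(profiles, design, bands = defaultBands(),
                        nSubsamples = 100, seed = 1) {
  if (nSessions(profiles) < 2L) stop("need >= 2 sessions", call. = FALSE)
  arr <- bandMeanArray(profiles, bands)
  P <- nParcels(profiles); nb <- length(bands@name)
  full <- matrix(iccCellwise(arr), P, nb)
  pm <- pairIndexMatrix(design)
  unrel <- which(is.na(pairIds(design)))
  if (!ncol(pm)) {   # no twins: every subsample is the full cohort
    return(structure(
      list(values = full, subsampleMean = full, nSubsamples = nSubsamples,
           bands = bands@name),
      class = "ICCMap"))
  }
  acc <- matrix(0, P, nb)
  withSeed(seed, {
    for (b in seq_len(nSubsamples)) {
      pick <- if (ncol(pm)) {
        pm[cbind(sample(c(1L, 2L), ncol(pm), replace = TRUE), seq_len(ncol(pm)))]
      } else integer()
      keep <- sort(c(pick, unrel))
      if (length(keep) < 3L) {
        stop("twin pruning leaves fewer than 3 subjects", call. = FALSE)
      }
      acc <- acc + matrix(iccCellwise(arr[keep, , , drop = FALSE]), P, nb)
    }
  })
  structure(
    list(values = full, subsampleMean = acc / nSubsamples,
         nSubsamples = nSubsamples, bands = bands@name),
    class = "ICCMap")
}

# Per-pair sufficient statistics of the double-entered cross-twin
# cross-session comparison, per cell. For pair p with session values
# a (T x C) and b (T x C) the double-entered sample is
# {(a_i, b_j), (b_j, a_i) : i, j in sessions}. Returns list of pairs x C
# matrices M1 = colSums(a) + colSums(b), M2 = colSums(a^2) + colSums(b^2),
# M3 = colSums(a) * colSums(b), from which the pooled double-entered
# Pearson correlation of any pair subset is
#   r = (Sxy - Sx^2 / n) / (Sxx - Sx^2 / n),
# with n = 2 T^2 m, Sx = T * sum(M1), Sxx = T * sum(M2), Sxy = 2 * sum(M3).
crossTwinStats <- function(arr, pairsIdx) {
  m <- ncol(pairsIdx); C <- dim(arr)[3]
  M1 <- matrix(NA_real_, m, C); M2 <- M1; M3 <- M1
  for (p in seq_len(m)) {
    a <- arr[pairsIdx[1L, p], , , drop = TRUE]
    b <- arr[pairsIdx[2L, p], , , drop = TRUE]
    if (is.null(dim(a))) {       # single cell: sessions x 1
      a <- matrix(a, ncol = 1L); b <- matrix(b, ncol = 1L)
    }
    sa <- colSums(a); sb <- colSums(b)
    M1[p, ] <- sa + sb
    M2[p, ] <- colSums(a^2) + colSums(b^2)
    M3[p, ] <- sa * sb
  }
  list(M1 = M1, M2 = M2, M3 = M3, nSess = dim(arr)[2])
}

# Pooled double-entered correlation per cell for a pair subset (logical or
# integer index into the rows of the stats matrices).
crossTwinRFromStats <- function(st, sel) {
  M1 <- st$M1[sel, , drop = FALSE]
  M2 <- st$M2[sel, , drop = FALSE]
  M3 <- st$M3[sel, , drop = FALSE]
  Tn <- st$nSess
  m <- nrow(M1)
  n <- 2 * Tn^2 * m
  Sx <- Tn * colSums(M1)
  Sxx <- Tn * colSums(M2)
  Sxy <- 2 * colSums(M3)
  num <- Sxy - Sx^2 / n
  den <- Sxx - Sx^2 / n
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

# ANOVA-ICC variant of the cross-twin correlation: one-way ICC with pairs as
# groups and all 2 * nSessions member-session values as replicates.
crossTwinICCCellwise <- function(arr, pairsIdx) {
  m <- ncol(pairsIdx); Tn <- dim(arr)[2]; C <- dim(arr)[3]
  obs <- array(NA_real_, c(m, 2L * Tn, C))
  for (p in seq_len(m)) {
    obs[p, seq_len(Tn), ] <- arr[pairsIdx[1L, p], , ]
    obs[p, Tn + seq_len(Tn), ] <- arr[pairsIdx[2L, p], , ]
  }
  iccCellwise(obs)
}

#' Cross-twin cross-session correlation
#'
#' For a given parcel and band, collects all 3 x 3 (sessions x sessions)
#' cross-twin value pairings over pairs of the requested zygosity,
#' double-enters them (both twin orderings) and returns the Pearson
#' correlation over the pooled pairings -- the default estimator of the
#' twin-pair trait correlation. The \code{"anova"} estimator instead uses a
#' one-way ICC with pairs as groups.
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class] with >= 2 pairs of the requested
#'   zygosity.
#' @param zygo \code{"MZ"} or \code{"DZ"}.
#' @param band band name (default \code{"alpha"}).
#' @param parcel parcel index (default 1).
#' @param bands a [BandScheme-class].
#' @param estimator \code{"pearson"} (double-entered; default) or
#'   \code{"anova"}.
#'
#' @return Correlation scalar.
#' @examples
#' des <- makeCohort(3, 3, 0)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' crossTwinCorrelation(prof, des, "MZ", band = "alpha", parcel = 2)
#' @export
crossTwinCorrelation <- function(profiles, design, zygo = c("MZ", "DZ"),
                                 band = "alpha", parcel = 1,
                                 bands = defaultBands(),
                                 estimator = c("pearson", "anova")) {
  zygo <- match.arg(zygo)
  estimator <- match.arg(estimator)
  pairsIdx <- pairIndexMatrix(design, zygo)
  if (ncol(pairsIdx) < 2L) {
    stop("need >= 2 pairs of zygosity ", zygo, call. = FALSE)
  }
  arr <- bandMeanArray(profiles, bands)
  bi <- match(band, bands@name)
  if (is.na(bi)) stop("unknown band: ", band, call. = FALSE)
  cell <- (bi - 1L) * nParcels(profiles) + parcel
  sub <- arr[, , cell, drop = FALSE]
  if (estimator == "pearson") {
    st <- crossTwinStats(sub, pairsIdx)
    unname(crossTwinRFromStats(st, seq_len(ncol(pairsIdx))))
  } else {
    unname(crossTwinICCCellwise(sub, pairsIdx))
  }
}

#' Falconer heritability from twin correlations
#'
#' \eqn{H^2 = 2 (r_{MZ} - r_{DZ})}, clipped to [0, 1] for mapping (raw value
#' preserved; Falconer estimates can exceed the bounds by sampling noise).
#'
#' @param rMz,rDz twin-pair correlations in [-1, 1].
#'
#' @return List with \code{h2} (clipped) and \code{raw}.
#' @examples
#' falconerH2(0.8, 0.4)$h2  # 0.8
#' @export
falconerH2 <- function(rMz, rDz) {
  if (any(abs(c(rMz, rDz)) > 1)) {
    stop("twin correlations must lie in [-1, 1]", call. = FALSE)
  }
  raw <- 2 * (rMz - rDz)
  list(h2 = pmin(1, pmax(0, raw)), raw = raw)
}

#' Falconer heritability map with permutation significance
#'
#' Per parcel and band: cross-twin cross-session correlations for MZ and DZ
#' pairs (double-entered Pearson over all session pairings) and the Falconer
#' estimate \eqn{2(r_{MZ} - r_{DZ})}. Significance is assessed by shuffling
#' zygosity labels across pairs (preserving pair structure) \code{nPerm}
#' times; one-tailed p-values use the +1 small-sample correction and are
#' BH-FDR adjusted across parcels within each band.
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class] with >= 2 MZ and >= 2 DZ pairs.
#' @param bands a [BandScheme-class] (default [defaultBands()]).
#' @param nPerm number of zygosity permutations (default 1000; values below
#'   100 are allowed but recorded as a warning in the result).
#' @param seed integer seed.
#'
#' @return List of class \code{"HeritabilityMap"} with parcels x bands
#'   matrices \code{h2}, \code{h2Raw}, \code{rMz}, \code{rDz}, \code{pPerm},
#'   \code{qFdr}, plus \code{bands} and \code{notes}.
#' @examples
#' des <- makeCohort(4, 4, 0)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' hm <- heritabilityMap(prof, des, nPerm = 50, seed = 2)
#' range(hm$h2)
#' @export
heritabilityMap <- function(profiles, design, bands = defaultBands(),
                            nPerm = 1000, seed = 1) {
  mz <- pairIndexMatrix(design, "MZ")
  dz <- pairIndexMatrix(design, "DZ")
  if (ncol(mz) < 2L || ncol(dz) < 2L) {
    stop("need >= 2 MZ and >= 2 DZ pairs", call. = FALSE)
  }
  notes <- character()
  if (nPerm < 100) notes <- c(notes, "nPerm < 100: permutation p unstable")
  arr <- bandMeanArray(profiles, bands)
  P <- nParcels(profiles); nb <- length(bands@name)
  allPairs <- cbind(mz, dz)
  isMz <- c(rep(TRUE, ncol(mz)), rep(FALSE, ncol(dz)))
  st <- crossTwinStats(arr, allPairs)
  rMz <- crossTwinRFromStats(st, isMz)
  rDz <- crossTwinRFromStats(st, !isMz)
  h2raw <- 2 * (rMz - rDz)
  nullGe <- numeric(length(h2raw))
  withSeed(seed, {
    for (k in seq_len(nPerm)) {
      lab <- sample(isMz)
      nullRaw <- 2 * (crossTwinRFromStats(st, lab) -
                        crossTwinRFromStats(st, !lab))
      nullGe <- nullGe + (nullRaw >= h2raw)
    }
  })
  pPerm <- (1 + nullGe) / (1 + nPerm)
  pMat <- matrix(pPerm, P, nb)
  qMat <- apply(pMat, 2L, function(p) stats::p.adjust(p, "BH"))
  structure(
    list(h2 = matrix(pmin(1, pmax(0, h2raw)), P, nb),
         h2Raw = matrix(h2raw, P, nb),
         rMz = matrix(rMz, P, nb), rDz = matrix(rDz, P, nb),
         pPerm = pMat, qFdr = qMat, bands = bands@name, notes = notes,
         nPerm = nPerm),
    class = "HeritabilityMap")
}

#' Robustness checks for the heritability map
#'
#' (i) Subsamples MZ pairs to the DZ pair count (averaged over
#' \code{nDraws} random draws) and correlates the resulting heritability
#' map with the full-cohort map; (ii) recomputes the map with the
#' ANOVA-ICC cross-twin estimator and correlates it with the default
#' double-entered Pearson map.
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param design a [CohortDesign-class].
#' @param bands a [BandScheme-class].
#' @param nDraws number of MZ subsampling draws (default 20).
#' @param seed integer seed.
#'
#' @return List: \code{subsampleCor}, \code{estimatorCor}, and the raw maps.
#' @examples
#' des <- makeCohort(5, 3, 0)
#' prof <- simulateProfiles(des, makeAtlas(10, 1), seed = 1)
#' heritabilityRobustness(prof, des, seed = 2)$estimatorCor
#' @export
heritabilityRobustness <- function(profiles, design, bands = defaultBands(),
                                   nDraws = 20, seed = 1) {
  mz <- pairIndexMatrix(design, "MZ")
  dz <- pairIndexMatrix(design, "DZ")
  if (ncol(mz) < 2L || ncol(dz) < 2L) {
    stop("need >= 2 MZ and >= 2 DZ pairs", call. = FALSE)
  }
  arr <- bandMeanArray(profiles, bands)
  allPairs <- cbind(mz, dz)
  isMz <- c(rep(TRUE, ncol(mz)), rep(FALSE, ncol(dz)))
  st <- crossTwinStats(arr, allPairs)
  rDz <- crossTwinRFromStats(st, !isMz)
  full <- 2 * (crossTwinRFromStats(st, isMz) - rDz)
  nSub <- min(ncol(mz), ncol(dz))
  sub <- withSeed(seed, {
    acc <- 0
    for (d in seq_len(nDraws)) {
      pick <- sample(which(isMz), nSub)
      sel <- rep(FALSE, length(isMz)); sel[pick] <- TRUE
      acc <- acc + 2 * (crossTwinRFromStats(st, sel) - rDz)
    }
    acc / nDraws
  })
  rMzIcc <- crossTwinICCCellwise(arr, mz)
  rDzIcc <- crossTwinICCCellwise(arr, dz)
  icc <- 2 * (rMzIcc - rDzIcc)
  list(
    subsampleCor = stats::cor(full, sub, use = "complete.obs"),
    estimatorCor = stats::cor(full, icc, use = "complete.obs"),
    fullMap = full, subsampledMap = sub, iccEstimatorMap = icc
  )
}

#' @export
print.ICCMap <- function(x, ...) {
  cat(sprintf("ICCMap: %d parcels x %d bands; subsample mean over %d twin-pruned subsamples\n",
              nrow(x$values), ncol(x$values), x$nSubsamples))
  invisible(x)
}

#' @export
print.HeritabilityMap <- function(x, ...) {
  cat(sprintf("HeritabilityMap: %d parcels x %d bands; mean H2 = %.2f (%d permutations)\n",
              nrow(x$h2), ncol(x$h2), mean(x$h2, na.rm = TRUE), x$nPerm))
  invisible(x)
}
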