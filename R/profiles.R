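#' Welch power spectral density estimate
#'
#' Estimates the power spectrum of a single time series by averaging
#' modified periodograms over sliding Hann-tapered segments (mean removed per
#' segment). With the default 2-s window the frequency resolution is 0.5 Hz,
#' so a recording sampled at >= 300 Hz yields the canonical 301-bin 0-150 Hz
#' profile grid.
#'
#' The returned values are power per bin (the periodogram density integrated
#' over one bin width), so that the summed spectrum of a zero-mean series
#' approximates its variance.
#'
#' @param series numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param windowS segment length in seconds (default 2).
#' @param overlapFrac fractional overlap between consecutive segments in
#'   [0, 1) (default 0.5).
#' @param demean remove each segment's mean before tapering (default TRUE).
#'
#' @return List with \code{freq} (Hz, resolution \code{1/windowS}) and
#'   \code{power} (non-negative, same length).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 300))
#' psd <- welchPsd(x, fs = 300)
#' psd$freq[which.max(psd$power)]  # 10 Hz
#' @export
welchPsd <- function(series, fs, windowS = 2, overlapFrac = 0.5,
                     demean = TRUE) {
  if (overlapFrac < 0 || overlapFrac >= 1) {
    stop("'overlapFrac' must lie in [0, 1)", call. = FALSE)
  }
  n <- round(windowS * fs)
  if (length(series) < n) {
    stop("series shorter than one window", call. = FALSE)
  }
  hop <- max(1L, round(n * (1 - overlapFrac)))
  starts <- seq(1L, length(series) - n + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))  # periodic Hann
  wnorm <- sum(w^2)
  nHalf <- n %/% 2L
  acc <- numeric(nHalf + 1L)
  for (s0 in starts) {
    seg <- series[s0:(s0 + n - 1L)]
    if (demean) seg <- seg - mean(seg)
    p <- Mod(stats::fft(w * seg))^2 / (n * wnorm)
    one <- p[seq_len(nHalf + 1L)]
    if (n %% 2L == 0L) {
      if (nHalf > 1L) one[2:nHalf] <- one[2:nHalf] + rev(p)[seq_len(nHalf - 1L)]
    } else {
      one[-1L] <- one[-1L] + rev(p)[seq_len(nHalf)]
    }
    acc <- acc + one
  }
  list(freq = (0:nHalf) * fs / n, power = acc / length(starts))
}

#' Extract band-limited features from spectral profiles
#'
#' Restricts the per-bin profiles to the bins falling inside each band
#' (\code{mode = "per_bin"}, the fingerprinting representation) or averages
#' power within each band (\code{mode = "band_mean"}, the representation used
#' for cortical ICC and heritability maps). Band membership is half-open
#' \code{[lo, hi)}; see [defaultBands()].
#'
#' @param profiles a [SpectralProfileSet-class].
#' @param bands a [BandScheme-class].
#' @param mode \code{"per_bin"} or \code{"band_mean"}.
#'
#' @return 4-way array subjects x sessions x parcels x features with a
#'   \code{"features"} attribute (data.frame of band / frequency per feature).
#' @examples
#' prof <- simulateProfiles(makeCohort(0, 0, 4), makeAtlas(10, 1),
#'                          nSessions = 2, seed = 1)
#' bm <- bandFeatures(prof, defaultBands(), "band_mean")
#' dim(bm)
#' @export
bandFeatures <- function(profiles, bands, mode = c("per_bin", "band_mean")) {
  mode <- match.arg(mode)
  stopifnot(is(profiles, "SpectralProfileSet"), is(bands, "BandScheme"))
  freq <- freqGrid(profiles)
  vals <- profileValues(profiles)
  nb <- length(bands@name)
  if (mode == "per_bin") {
    idx <- lapply(seq_len(nb), function(i) {
      bandBinIndices(freq, bands@lo[i], bands@hi[i])
    })
    allIdx <- unlist(idx)
    out <- vals[, , , allIdx, drop = FALSE]
    feat <- data.frame(
      band = rep(bands@name, lengths(idx)),
      freq = freq[allIdx]
    )
  } else {
    d <- dim(vals)
    out <- array(NA_real_, c(d[1], d[2], d[3], nb))
    for (i in seq_len(nb)) {
      sel <- bandBinIndices(freq, bands@lo[i], bands@hi[i])
      sub <- vals[, , , sel, drop = FALSE]
      out[, , , i] <- rowMeans(sub, dims = 3L)
    }
    feat <- data.frame(band = bands@name, freq = NA_real_)
  }
  attr(out, "features") <- feat
  out
}

#' Differential stability of regional gene expression across donors
#'
#' For every gene, the mean over all donor pairs of the Spearman rank
#' correlation between the two donors' regional expression vectors. Genes
#' that are constant across parcels in any donor have undefined stability and
#' are returned as \code{NA} (flagged, not dropped).
#'
#' @param donorExpr list (length >= 2) of parcels x genes matrices with
#'   identical dimensions and gene ordering.
#'
#' @return Numeric vector of per-gene stability in [-1, 1]; attribute
#'   \code{"undefined"} holds the indices of flagged genes.
#' @examples
#' d <- replicate(3, matrix(rnorm(50), 10, 5), simplify = FALSE)
#' differentialStability(d)
#' @export
differentialStability <- function(donorExpr) {
  if (!is.list(donorExpr) || length(donorExpr) < 2L) {
    stop("need at least two donors", call. = FALSE)
  }
  dims <- vapply(donorExpr, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("all donors must share parcel/gene dimensions", call. = FALSE)
  }
  ranks <- lapply(donorExpr, function(m) apply(m, 2L, rank))
  constant <- Reduce(`|`, lapply(donorExpr, function(m) {
    apply(m, 2L, function(x) max(x) == min(x))
  }))
  nG <- ncol(donorExpr[[1]])
  acc <- numeric(nG)
  nPairs <- 0L
  for (i in seq_along(ranks)) {
    for (j in seq_along(ranks)) {
      if (j <= i) next
      acc <- acc + colPearson(ranks[[i]], ranks[[j]])
      nPairs <- nPairs + 1L
    }
  }
  ds <- acc / nPairs
  ds[constant] <- NA_real_
  attr(ds, "undefined") <- which(constant)
  ds
}

#' Filter genes by differential stability
#'
#' Retains genes whose differential stability exceeds the threshold, in their
#' original order. The default cutoff of 0.1 is the conventional choice for
#' donor-averaged microarray atlases.
#'
#' @param expr a [GeneExpressionMatrix-class] with populated stability values.
#' @param threshold stability cutoff; genes with \code{ds > threshold} are
#'   kept (default 0.1). Genes with undefined (\code{NA}) stability are
#'   excluded and counted in the result's metadata.
#'
#' @return A [GeneExpressionMatrix-class] restricted to the retained genes.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' truth <- makeGroundTruth(atlas, nGenes = 50, seed = 1)
#' expr <- simulateExpression(atlas, 50, truth, seed = 1)
#' filterByDS(expr)
#' @export
filterByDS <- function(expr, threshold = 0.1) {
  stopifnot(is(expr, "GeneExpressionMatrix"))
  ds <- expr@ds
  keep <- which(!is.na(ds) & ds > threshold)
  if (!length(keep)) {
    stop("no genes exceed the differential-stability threshold", call. = FALSE)
  }
  meta <- expr@meta
  meta$dsThreshold <- threshold
  meta$nDroppedUndefined <- sum(is.na(ds))
  new("GeneExpressionMatrix",
      values = expr@values[, keep, drop = FALSE],
      geneIds = expr@geneIds[keep],
      ds = ds[keep],
      meta = meta)
}
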