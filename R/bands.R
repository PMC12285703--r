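#' Construct a frequency-band scheme
#'
#' @param name character vector of band names.
#' @param lo,hi numeric vectors of band edges in Hz (\code{lo < hi}).
#'
#' @return A [BandScheme-class] object.
#' @examples
#' bandScheme(c("alpha", "beta"), c(8, 13), c(13, 30))
#' @export
bandScheme <- function(name, lo, hi) {
  new("BandScheme", name = as.character(name), lo = as.numeric(lo),
      hi = as.numeric(hi))
}

#' The six canonical electrophysiological frequency bands
#'
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz),
#' gamma (30-50 Hz) and high gamma (50-150 Hz). Bands are half-open
#' \code{[lo, hi)}; the shared printed edges therefore belong to the upper
#' band, and 150 Hz belongs to high gamma when the frequency grid tops out
#' there.
#'
#' @return A [BandScheme-class] with six bands.
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  bandScheme(
    c("delta", "theta", "alpha", "beta", "gamma", "highgamma"),
    c(1, 4, 8, 13, 30, 50),
    c(4, 8, 13, 30, 50, 150)
  )
}

# Indices of frequency bins belonging to [lo, hi); a band whose upper edge
# equals the top of the grid includes that edge, so the six canonical bands
# partition the 1-150 Hz axis.
bandBinIndices <- function(freq, lo, hi) {
  if (lo < min(freq) || hi > max(freq)) {
    stop(sprintf("band [%g, %g) lies outside the frequency grid [%g, %g]",
                 lo, hi, min(freq), max(freq)), call. = FALSE)
  }
  sel <- freq >= lo & freq < hi
  if (hi == max(freq)) sel <- sel | freq == hi
  which(sel)
}

# Map each frequency bin to the band containing it (NA outside all bands).
binBandAssignment <- function(freq, bands) {
  out <- rep(NA_integer_, length(freq))
  for (i in seq_along(bands@name)) {
    out[bandBinIndices(freq, bands@lo[i], bands@hi[i])] <- i
  }
  out
}
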