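#' Parcellated cortical atlas
#'
#' Holds parcel identifiers, unit-sphere centroid coordinates and hemisphere
#' labels for a bilateral cortical parcellation (a Schaefer-style atlas at
#' desk scale). Centroids follow the spherical-registration convention:
#' each hemisphere occupies a complete unit sphere and the right hemisphere
#' is stored mirrored into register with the left, so homotopic parcels lie
#' close together and spherical rotations used by the spin test are well
#' defined without hemisphere-boundary artifacts.
#'
#' @slot parcelId integer vector of unique parcel identifiers.
#' @slot centroid numeric matrix (parcels x 3) of unit-norm coordinates.
#' @slot hemisphere character vector, one of \code{"L"} or \code{"R"} per
#'   parcel.
#' @slot regionGroup character vector of coarse region labels (used by the
#'   developmental analysis); may be \code{NA}.
#'
#' @seealso [makeAtlas()]
#' @export
setClass("ParcelAtlas",
  representation(
    parcelId = "integer",
    centroid = "matrix",
    hemisphere = "character",
    regionGroup = "character"
  )
)

setValidity("ParcelAtlas", function(object) {
  n <- length(object@parcelId)
  msg <- character()
  if (anyDuplicated(object@parcelId)) msg <- c(msg, "parcel ids must be unique")
  if (!is.numeric(object@centroid) || nrow(object@centroid) != n ||
      ncol(object@centroid) != 3L) {
    msg <- c(msg, "centroid must be a numeric parcels x 3 matrix")
  } else {
    norms <- sqrt(rowSums(object@centroid^2))
    if (any(abs(norms - 1) > 1e-9)) {
      msg <- c(msg, "centroids must have unit norm (within 1e-9)")
    }
  }
  if (length(object@hemisphere) != n || !all(object@hemisphere %in% c("L", "R"))) {
    msg <- c(msg, "every parcel needs a hemisphere label in {L, R}")
  }
  if (length(object@regionGroup) != n) {
    msg <- c(msg, "regionGroup must have one entry per parcel")
  }
  if (length(msg)) msg else TRUE
})

#' Twin-cohort design
#'
#' Subject/pair/zygosity bookkeeping for twin analyses. Each non-missing pair
#' id occurs exactly twice, both members of a pair share zygosity, and
#' unrelated subjects carry a missing pair id.
#'
#' @slot subjectId character vector of unique subject labels.
#' @slot pairId character vector of pair labels (\code{NA} for unrelated).
#' @slot zygosity character vector in \code{{"MZ", "DZ", "UNRELATED"}}.
#'
#' @seealso [makeCohort()]
#' @export
setClass("CohortDesign",
  representation(
    subjectId = "character",
    pairId = "character",
    zygosity = "character"
  )
)

setValidity("CohortDesign", function(object) {
  n <- length(object@subjectId)
  msg <- character()
  if (anyDuplicated(object@subjectId)) msg <- c(msg, "subject ids must be unique")
  if (length(object@pairId) != n || length(object@zygosity) != n) {
    msg <- c(msg, "pairId and zygosity must have one entry per subject")
  } else {
    if (!all(object@zygosity %in% c("MZ", "DZ", "UNRELATED"))) {
      msg <- c(msg, "zygosity must be MZ, DZ or UNRELATED")
    }
    paired <- !is.na(object@pairId)
    if (any(object@zygosity[!paired] != "UNRELATED")) {
      msg <- c(msg, "subjects without a pair id must be UNRELATED")
    }
    if (any(object@zygosity[paired] == "UNRELATED")) {
      msg <- c(msg, "UNRELATED subjects must have a missing pair id")
    }
    if (any(paired)) {
      tab <- table(object@pairId[paired])
      if (any(tab != 2L)) msg <- c(msg, "each pair id must occur exactly twice")
      zyg <- split(object@zygosity[paired], object@pairId[paired])
      if (any(!vapply(zyg, function(z) length(unique(z)) == 1L, logical(1)))) {
        msg <- c(msg, "both members of a pair must share zygosity")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Planted ground truth for the synthetic-data generator
#'
#' Collects the simulation parameters whose recovery the test-suite checks:
#' the additive-genetic (\code{h2}) and shared-environment (\code{c2})
#' variance fractions of the classical twin model, the between-session noise
#' scale, the planted cortical latent gradient, the planted gene and
#' frequency-band weight vectors of the low-rank gene-trait covariance, the
#' enriched cell-type label, and the planted developmental slope.
#'
#' @slot h2 numeric scalar in [0, 1]: narrow-sense heritability fraction.
#' @slot c2 numeric scalar: shared-environment fraction; \code{h2 + c2 <= 1}.
#' @slot sessionNoiseSd numeric scalar: within-subject between-session noise
#'   standard deviation (trait components have unit variance).
#' @slot latentMap numeric vector (parcels): planted covariance gradient.
#' @slot geneWeights numeric vector (genes): planted gene loadings.
#' @slot bandWeights numeric vector (bands): planted band loadings.
#' @slot enrichedCelltype character scalar: label of the planted enriched
#'   cell-type set.
#' @slot devSlope numeric scalar: planted developmental slope per stage.
#'
#' @seealso [makeGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    h2 = "numeric",
    c2 = "numeric",
    sessionNoiseSd = "numeric",
    latentMap = "numeric",
    geneWeights = "numeric",
    bandWeights = "numeric",
    enrichedCelltype = "character",
    devSlope = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (object@h2 < 0 || object@c2 < 0 || object@h2 + object@c2 > 1 + 1e-12) {
    msg <- c(msg, "h2 and c2 must be non-negative with h2 + c2 <= 1")
  }
  if (object@sessionNoiseSd < 0) msg <- c(msg, "sessionNoiseSd must be >= 0")
  if (!all(is.finite(object@latentMap))) msg <- c(msg, "latentMap must be finite")
  if (length(msg)) msg else TRUE
})

#' Frequency-band scheme
#'
#' Ordered set of named frequency bands. Band membership is half-open
#' \code{[lo, hi)} so that adjacent bands sharing a printed edge partition the
#' frequency axis; a band whose upper edge coincides with the top of the
#' frequency grid additionally includes that edge.
#'
#' @slot name character vector of unique band names.
#' @slot lo numeric vector of lower edges (Hz).
#' @slot hi numeric vector of upper edges (Hz).
#'
#' @seealso [bandScheme()], [defaultBands()]
#' @export
setClass("BandScheme",
  representation(name = "character", lo = "numeric", hi = "numeric")
)

setValidity("BandScheme", function(object) {
  msg <- character()
  n <- length(object@name)
  if (anyDuplicated(object@name)) msg <- c(msg, "band names must be unique")
  if (length(object@lo) != n || length(object@hi) != n) {
    msg <- c(msg, "name, lo and hi must have equal length")
  } else if (any(object@lo >= object@hi)) {
    msg <- c(msg, "each band needs lo < hi")
  }
  if (length(msg)) msg else TRUE
})

#' Spectral profile set (brain-fingerprints)
#'
#' Power-spectral-density profiles for a cohort: a 4-way array of
#' non-negative power values indexed by subject, recording session, cortical
#' parcel and frequency bin.
#'
#' @slot values numeric 4-way array: subjects x sessions x parcels x bins.
#' @slot freq numeric vector of strictly increasing bin frequencies (Hz).
#' @slot subjectIds character vector of subject labels.
#' @slot sessionIds character vector of session labels.
#' @slot meta list of provenance metadata (seed, generator parameters).
#'
#' @seealso [simulateProfiles()], [bandFeatures()]
#' @export
setClass("SpectralProfileSet",
  representation(
    values = "array",
    freq = "numeric",
    subjectIds = "character",
    sessionIds = "character",
    meta = "list"
  )
)

setValidity("SpectralProfileSet", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 4L) {
    msg <- c(msg, "values must be a 4-way array (subjects x sessions x parcels x bins)")
  } else {
    if (length(object@subjectIds) != d[1]) msg <- c(msg, "subjectIds length must match dim 1")
    if (length(object@sessionIds) != d[2]) msg <- c(msg, "sessionIds length must match dim 2")
    if (length(object@freq) != d[4]) msg <- c(msg, "freq length must match dim 4")
  }
  if (is.unsorted(object@freq, strictly = TRUE)) {
    msg <- c(msg, "freq must be strictly increasing")
  }
  if (any(object@values < 0)) msg <- c(msg, "power values must be non-negative")
  if (anyNA(object@values)) msg <- c(msg, "no missing subject/session cells allowed")
  if (length(msg)) msg else TRUE
})

#' Parcellated gene-expression matrix
#'
#' Donor-averaged regional gene expression with per-gene differential
#' stability, the mean across donor pairs of the Spearman correlation between
#' the two donors' regional expression profiles of that gene.
#'
#' @slot values numeric matrix: parcels x genes.
#' @slot geneIds character vector of unique gene labels.
#' @slot ds numeric vector of per-gene differential stability in [-1, 1]
#'   (\code{NA} where undefined, e.g. a gene constant across parcels in some
#'   donor).
#' @slot meta list of provenance metadata.
#'
#' @seealso [simulateExpression()], [differentialStability()], [filterByDS()]
#' @export
setClass("GeneExpressionMatrix",
  representation(
    values = "matrix",
    geneIds = "character",
    ds = "numeric",
    meta = "list"
  )
)

setValidity("GeneExpressionMatrix", function(object) {
  msg <- character()
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (ncol(object@values) != length(object@geneIds)) {
    msg <- c(msg, "one gene id per column required")
  }
  if (length(object@ds) != length(object@geneIds)) {
    msg <- c(msg, "one differential-stability value per gene required")
  } else if (any(abs(object@ds) > 1 + 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "differential stability must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Spatial-autocorrelation-preserving permutation null (spin test)
#'
#' A table of parcel permutations obtained by rotating parcel centroids on
#' the sphere (mirrored rotation across hemispheres) and reassigning rotated
#' to original parcels by minimum-total-distance Hungarian assignment.
#'
#' @slot permutations integer matrix: permutations x parcels; each row is a
#'   bijection on parcel indices.
#' @slot rotations numeric array 3 x 3 x permutations of the left-hemisphere
#'   rotation matrices (the right hemisphere uses the x-mirrored rotation).
#' @slot seed integer seed the spins were generated from.
#'
#' @seealso [generateSpins()], [spatialCorrTest()]
#' @export
setClass("SpinNull",
  representation(
    permutations = "matrix",
    rotations = "array",
    seed = "integer"
  )
)

setValidity("SpinNull", function(object) {
  msg <- character()
  p <- ncol(object@permutations)
  ok <- apply(object@permutations, 1L, function(r) all(sort(r) == seq_len(p)))
  if (!all(ok)) msg <- c(msg, "every row must be a permutation of parcel indices")
  dets <- apply(object@rotations, 3L, det)
  if (any(abs(dets - 1) > 1e-9)) {
    msg <- c(msg, "rotation matrices must have determinant +1 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Developmental gene-expression set
#'
#' Regional gene expression across ordered developmental stages (a
#' BrainSpan-style table): a 3-way array regions x stages x genes, with
#' stages coded as equally spaced integer indices.
#'
#' @slot values numeric array: regions x stages x genes.
#' @slot regions character vector of region labels.
#' @slot stages integer vector of strictly increasing stage indices.
#' @slot geneIds character vector of gene labels.
#' @slot meta list of provenance metadata (e.g. the designated null region of
#'   the generator).
#'
#' @seealso [simulateDevExpression()], [devGeneScores()]
#' @export
setClass("DevExpressionSet",
  representation(
    values = "array",
    regions = "character",
    stages = "integer",
    geneIds = "character",
    meta = "list"
  )
)

setValidity("DevExpressionSet", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L) {
    msg <- c(msg, "values must be a 3-way array (regions x stages x genes)")
  } else {
    if (length(object@regions) != d[1]) msg <- c(msg, "one region label per row required")
    if (length(object@stages) != d[2]) msg <- c(msg, "one stage index per stage required")
    if (length(object@geneIds) != d[3]) msg <- c(msg, "one gene id per gene required")
  }
  if (is.unsorted(object@stages, strictly = TRUE)) {
    msg <- c(msg, "stage indices must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Partial least squares correlation model
#'
#' Result of the singular value decomposition of the cross-covariance of two
#' column-standardised parcel-indexed matrices \eqn{X} (e.g. gene expression)
#' and \eqn{Y} (e.g. band-wise ICC maps): paired weight vectors, singular
#' values, covariance-explained fractions and parcel score patterns, with
#' optional spin p-values, bootstrap intervals and correlation loadings.
#'
#' @slot u numeric matrix: X-variable weights per component (columns
#'   unit-norm).
#' @slot v numeric matrix: Y-variable weights per component.
#' @slot s numeric vector of non-increasing singular values.
#' @slot covExplained numeric vector: \eqn{s^2 / \sum s^2}.
#' @slot xScores,yScores numeric matrices: parcels x components.
#' @slot xLoadings,yLoadings numeric matrices: correlation of each variable's
#'   parcel map with the opposite block's score pattern (filled by
#'   [plsLoadings()]).
#' @slot pSpin numeric vector of per-component spin p-values (filled by
#'   [plsSignificance()]).
#' @slot bootCI numeric matrix (components x 2) of bootstrap intervals for
#'   covariance explained (filled by [plsBootstrap()]).
#' @slot meta list: column means/sds used for z-scoring, variable ids.
#'
#' @seealso [fitPLS()]
#' @export
setClass("PLSModel",
  representation(
    u = "matrix",
    v = "matrix",
    s = "numeric",
    covExplained = "numeric",
    xScores = "matrix",
    yScores = "matrix",
    xLoadings = "matrix",
    yLoadings = "matrix",
    pSpin = "numeric",
    bootCI = "matrix",
    meta = "list"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character()
  if (length(object@s) && is.unsorted(rev(object@s))) {
    msg <- c(msg, "singular values must be non-increasing")
  }
  if (length(object@covExplained) &&
      abs(sum(object@covExplained) - 1) > 1e-8) {
    msg <- c(msg, "covExplained must sum to 1")
  }
  un <- sqrt(colSums(object@u^2))
  vn <- sqrt(colSums(object@v^2))
  if (any(abs(un - 1) > 1e-8) || any(abs(vn - 1) > 1e-8)) {
    msg <- c(msg, "columns of u and v must be unit-norm")
  }
  if (length(msg)) msg else TRUE
})
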