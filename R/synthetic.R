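# Synthetic-data generators. Every generator is a pure function of its
# arguments including the seed; defaults reflect the study conditions the
# pipeline was designed for (89-subject twin cohort, 200 parcels, 0-150 Hz
# at 0.5 Hz resolution, six donors).

#' Generate a bilateral spherical parcel atlas
#'
#' Places \code{nParcels/2} centroids per hemisphere quasi-uniformly on the
#' full unit sphere using a Fibonacci lattice with Gaussian jitter
#' (renormalised), so different seeds give different but equally regular
#' parcellations. Coordinates follow the spherical-registration convention:
#' each hemisphere occupies its own complete sphere and the right
#' hemisphere is stored mirrored into register with the left, so homotopic
#' parcels of the two hemispheres lie close together on the common
#' reference sphere. All spatial kernels, parcel distances and spin
#' rotations operate on these reference coordinates (a rotation applied to
#' both hemispheres in reference coordinates corresponds to physically
#' mirrored rotations, which keeps homotopic structure).
#'
#' @param nParcels even integer >= 4; total parcel count (split across
#'   hemispheres).
#' @param seed integer seed.
#' @param jitterSd standard deviation of the centroid jitter (default 0.06).
#'
#' @return A [ParcelAtlas-class].
#' @examples
#' makeAtlas(100, seed = 1)
#' @export
makeAtlas <- function(nParcels, seed, jitterSd = 0.06) {
  stopifnotScalarCount(nParcels, "nParcels", min = 4L)
  if (nParcels %% 2L != 0L) {
    stop("'nParcels' must be even (parcels are split across hemispheres)",
         call. = FALSE)
  }
  m <- nParcels %/% 2L
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m              # full-sphere Fibonacci lattice
  r <- sqrt(pmax(0, 1 - z^2))
  base <- cbind(r * cos(golden * i), r * sin(golden * i), z)
  jitterPts <- function(pts, sd) {
    pts <- pts + matrix(stats::rnorm(length(pts), sd = sd), ncol = 3L)
    pts / sqrt(rowSums(pts^2))
  }
  withSeed(seed, {
    left <- jitterPts(base, jitterSd)
    # approximately homotopic: right parcels sit near their left
    # counterparts on the reference sphere
    right <- jitterPts(left, jitterSd / 4)
    cen <- rbind(left, right)
    hemi <- rep(c("L", "R"), each = m)
    # coarse lobes from the sagittal-plane angle, for the developmental stage
    ang <- atan2(cen[, 3], cen[, 2])
    lobe <- cut(ang, breaks = c(-pi, -pi / 2, 0, pi / 2, pi),
                labels = c("temporal", "occipital", "parietal", "frontal"),
                include.lowest = TRUE)
    new("ParcelAtlas",
        parcelId = seq_len(nParcels),
        centroid = unname(cen),
        hemisphere = hemi,
        regionGroup = as.character(lobe))
  })
}

#' Generate a twin-cohort design
#'
#' Defaults reproduce the reference cohort composition: 17 monozygotic
#' pairs, 11 dizygotic pairs and 33 unrelated individuals (89 subjects).
#'
#' @param nMzPairs,nDzPairs,nUnrelated non-negative counts.
#'
#' @return A [CohortDesign-class].
#' @examples
#' makeCohort()            # the 89-subject reference design
#' makeCohort(1, 1, 0)
#' @export
makeCohort <- function(nMzPairs = 17, nDzPairs = 11, nUnrelated = 33) {
  stopifnotScalarCount(nMzPairs, "nMzPairs")
  stopifnotScalarCount(nDzPairs, "nDzPairs")
  stopifnotScalarCount(nUnrelated, "nUnrelated")
  nTot <- 2L * nMzPairs + 2L * nDzPairs + nUnrelated
  if (nTot < 2L) stop("cohort needs at least 2 subjects", call. = FALSE)
  subjectId <- sprintf("S%03d", seq_len(nTot))
  pairId <- rep(NA_character_, nTot)
  zyg <- rep("UNRELATED", nTot)
  k <- 0L
  if (nMzPairs > 0) {
    idx <- k + seq_len(2L * nMzPairs)
    pairId[idx] <- rep(sprintf("MZ%02d", seq_len(nMzPairs)), each = 2L)
    zyg[idx] <- "MZ"
    k <- k + 2L * nMzPairs
  }
  if (nDzPairs > 0) {
    idx <- k + seq_len(2L * nDzPairs)
    pairId[idx] <- rep(sprintf("DZ%02d", seq_len(nDzPairs)), each = 2L)
    zyg[idx] <- "DZ"
  }
  new("CohortDesign", subjectId = subjectId, pairId = pairId, zygosity = zyg)
}

#' Construct planted ground truth for the generators
#'
#' Builds the parameter bundle the recovery tests check against. The planted
#' cortical latent gradient is a smooth field over the atlas (an
#' anterior-posterior trend plus a spatially autocorrelated component,
#' standardised to zero mean / unit variance); planted gene weights are
#' standard normal.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nGenes number of genes to plant weights for.
#' @param h2 narrow-sense heritability fraction (default 0.6).
#' @param c2 shared-environment fraction (default 0.1); \code{h2 + c2 <= 1}.
#' @param sessionNoiseSd between-session noise scale relative to unit trait
#'   variance (default 0.3, i.e. session noise well below trait variance, as
#'   expected for stable spectral profiles).
#' @param bandWeights numeric vector, one per band of the scheme the profiles
#'   will use. The default (six bands) makes the planted saliency gradient
#'   co-oriented across bands and strongest in alpha/beta, the canonically
#'   most salient ranges: \code{c(0.10, 0.15, 0.50, 0.40, 0.25, 0.15)}.
#' @param enrichedCelltype label of the cell-type set planted as enriched
#'   (default \code{"excitatory"}).
#' @param devSlope planted per-stage developmental slope (default 0.5).
#' @param seed integer seed (for the latent map and gene weights).
#'
#' @return A [GroundTruth-class].
#' @examples
#' makeGroundTruth(makeAtlas(20, 1), nGenes = 100, seed = 1)
#' @export
makeGroundTruth <- function(atlas, nGenes, h2 = 0.6, c2 = 0.1,
                            sessionNoiseSd = 0.3, bandWeights = NULL,
                            enrichedCelltype = "excitatory",
                            devSlope = 0.5, seed = 1) {
  stopifnot(is(atlas, "ParcelAtlas"))
  stopifnotScalarCount(nGenes, "nGenes", min = 1L)
  if (is.null(bandWeights)) bandWeights <- c(0.10, 0.15, 0.50, 0.40, 0.25, 0.15)
  withSeed(childSeed(seed, 17L), {
    cen <- centroids(atlas)
    smooth <- spatialField(cen, 1L, ell = 0.5)[, 1]
    lm0 <- cen[, 2] + 0.7 * smooth
    latentMap <- as.numeric(scale(lm0))
    geneWeights <- stats::rnorm(nGenes)
    new("GroundTruth",
        h2 = h2, c2 = c2, sessionNoiseSd = sessionNoiseSd,
        latentMap = latentMap, geneWeights = geneWeights,
        bandWeights = bandWeights,
        enrichedCelltype = enrichedCelltype, devSlope = devSlope)
  })
}

# Draw spatially autocorrelated unit-variance Gaussian fields over parcel
# centroids; exponential kernel exp(-d/ell) on 3-D chord distance by
# default, Gaussian kernel exp(-d^2/(2 ell^2)) for differentiable fields.
spatialField <- function(cen, nFields, ell, kernel = c("exponential",
                                                       "gaussian")) {
  kernel <- match.arg(kernel)
  if (ell <= 0) stop("'autocorrLength' must be positive", call. = FALSE)
  d <- as.matrix(stats::dist(cen))
  K <- if (kernel == "exponential") exp(-d / ell) else exp(-d^2 / (2 * ell^2))
  L <- chol(K + diag(1e-6, nrow(K)))
  out <- t(L) %*% matrix(stats::rnorm(nrow(cen) * nFields), nrow(cen), nFields)
  unname(out) / sqrt(1 + 1e-6)
}

#' Simulate spatially autocorrelated cortical maps
#'
#' Unit-variance Gaussian random fields over the parcel centroids, used for
#' null-calibration studies of map-to-map statistics. The Gaussian kernel
#' (default) yields differentiable, cortical-map-like fields; the
#' exponential kernel yields rougher fields.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nMaps number of independent maps.
#' @param ell autocorrelation length (chord distance on the unit sphere;
#'   default 0.6).
#' @param kernel \code{"gaussian"} (default) or \code{"exponential"}.
#' @param seed integer seed.
#'
#' @return parcels x nMaps numeric matrix.
#' @examples
#' m <- simulateSmoothMaps(makeAtlas(20, 1), 3, seed = 1)
#' dim(m)
#' @export
simulateSmoothMaps <- function(atlas, nMaps, ell = 0.6,
                               kernel = c("gaussian", "exponential"),
                               seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(is(atlas, "ParcelAtlas"))
  withSeed(seed, spatialField(centroids(atlas), nMaps, ell, kernel))
}

# 1/f-like baseline spectrum shared by all subjects (arbitrary power units);
# large offset keeps simulated power strictly positive.
baselineSpectrum <- function(freq) 20 + 30 / (1 + freq / 2)

# Draw an n x d matrix with the classical twin covariance applied along
# rows: MZ co-twins share the draw, DZ co-twins correlate 0.5 (bivariate
# construction), pair members share the common-environment part.
twinStructuredDraw <- function(nS, d, pairs, zyg, h2, c2) {
  g <- matrix(stats::rnorm(nS * d), nS)
  cc <- matrix(stats::rnorm(nS * d), nS)
  e <- matrix(stats::rnorm(nS * d), nS)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    if (zyg[a] == "MZ") {
      g[b, ] <- g[a, ]
    } else {
      g[b, ] <- 0.5 * g[a, ] + sqrt(0.75) * g[b, ]
    }
    cc[b, ] <- cc[a, ]
  }
  sqrt(h2) * g + sqrt(c2) * cc + sqrt(pmax(0, 1 - h2 - c2)) * e
}

#' Simulate twin-structured spectral profiles
#'
#' Generates a [SpectralProfileSet-class] under the classical additive twin
#' model. For each subject, parcel and frequency bin the latent trait is
#' \deqn{T = \sqrt{h^2}\,g + \sqrt{c^2}\,c + \sqrt{1 - h^2 - c^2}\,e,}
#' where monozygotic co-twins share the genetic draw \eqn{g} exactly,
#' dizygotic co-twins share it with correlation 0.5 (bivariate construction),
#' pair members share the common-environment draw \eqn{c}, and \eqn{e} is
#' unique. Each session adds independent Gaussian noise with standard
#' deviation \code{sessionNoiseSd}. Traits are scaled by a parcel-by-band
#' amplitude \eqn{A = \max(0.2,\; 1 + w_{band} \cdot \ell_{parcel})} that
#' embeds the planted latent gradient \eqn{\ell} with band weights \eqn{w},
#' and added to a 1/f-like baseline, so expected cross-twin correlations are
#' \eqn{r_{MZ} = (h^2 + c^2)\,a} and \eqn{r_{DZ} = (h^2/2 + c^2)\,a} with
#' attenuation \eqn{a = A^2 / (A^2 + \sigma^2_{session})}.
#'
#' @param design a [CohortDesign-class].
#' @param atlas a [ParcelAtlas-class].
#' @param bands a [BandScheme-class] (default [defaultBands()]).
#' @param truth a [GroundTruth-class]; default
#'   \code{makeGroundTruth(atlas, nGenes = 1, seed = seed)}.
#' @param nSessions number of recording sessions (default 3, >= 2).
#' @param seed integer seed.
#' @param freq frequency grid in Hz (default \code{seq(0, 150, 0.5)}, the
#'   301-bin profile grid).
#' @param nFactors number of smooth global trait factors (default 8).
#' @param factorShare fraction of the trait variance carried by the global
#'   factors (default 0.7). Real spectral profiles are dominated by a few
#'   subject-level factors (overall power, alpha-peak amplitude, spectral
#'   slope) that are smooth over frequency and cortex; routing most of the
#'   trait variance through \code{nFactors} such factors (each with the same
#'   twin decomposition, so per-feature twin correlations are unchanged)
#'   gives between-subject profile similarities a realistic spread instead
#'   of the degenerate concentration an independent-feature model produces.
#'
#' @return A [SpectralProfileSet-class]; \code{metaData()} records the seed
#'   and generator parameters.
#' @examples
#' prof <- simulateProfiles(makeCohort(2, 2, 2), makeAtlas(10, 1),
#'                          nSessions = 2, seed = 7)
#' prof
#' @export
simulateProfiles <- function(design, atlas, bands = defaultBands(),
                             truth = NULL, nSessions = 3, seed = 1,
                             freq = seq(0, 150, by = 0.5),
                             nFactors = 8, factorShare = 0.7) {
  stopifnot(is(design, "CohortDesign"), is(atlas, "ParcelAtlas"))
  stopifnotScalarCount(nSessions, "nSessions", min = 2L)
  if (is.null(truth)) makeGroundTruth(atlas, nGenes = 1L, seed = seed) -> truth
  stopifnot(is(truth, "GroundTruth"))
  h2 <- truth@h2; c2 <- truth@c2
  if (h2 + c2 > 1 + 1e-12) stop("h2 + c2 must not exceed 1", call. = FALSE)
  lm <- truth@latentMap
  if (length(lm) != nParcels(atlas)) {
    stop("truth latentMap length must match the atlas", call. = FALSE)
  }
  bw <- truth@bandWeights
  if (length(bw) != length(bands@name)) {
    stop("truth bandWeights length must match the band scheme", call. = FALSE)
  }
  nS <- nSubjects(design)
  P <- nParcels(atlas)
  nF <- length(freq)
  assign <- binBandAssignment(freq, bands)
  wBin <- ifelse(is.na(assign), 0, bw[assign])
  A <- pmax(0.2, 1 + outer(lm, wBin))          # P x F amplitude
  aVec <- as.vector(A)                          # parcel fastest
  baseVec <- rep(baselineSpectrum(freq), each = P)
  pf <- P * nF

  zyg <- zygosity(design)
  pid <- pairIds(design)
  pairs <- pairIndexMatrix(design)

  withSeed(seed, {
    # smooth factor basis: spatial GP over centroids x spectral GP over
    # frequency, scaled to unit per-feature variance
    dF <- abs(outer(freq, freq, "-"))
    Lf <- chol(exp(-dF / 15) + diag(1e-8, nF))
    bSpec <- t(t(Lf) %*% matrix(stats::rnorm(nF * nFactors), nF))  # K x F
    bSpat <- t(spatialField(centroids(atlas), nFactors, ell = 0.8)) # K x P
    B <- matrix(NA_real_, nFactors, pf)
    for (k in seq_len(nFactors)) B[k, ] <- as.vector(outer(bSpat[k, ], bSpec[k, ]))
    B <- sweep(B, 2L, sqrt(pmax(colSums(B^2), 1e-12)), "/")
    fac <- twinStructuredDraw(nS, nFactors, pairs, zyg, h2, c2)
    iid <- twinStructuredDraw(nS, pf, pairs, zyg, h2, c2)
    trait <- sqrt(factorShare) * (fac %*% B) + sqrt(1 - factorShare) * iid
    core <- sweep(trait, 2L, aVec, "*")
    vals <- array(NA_real_, c(nS, nSessions, P, nF))
    for (t in seq_len(nSessions)) {
      vt <- core + truth@sessionNoiseSd * matrix(stats::rnorm(nS * pf), nS)
      vt <- sweep(vt, 2L, baseVec, "+")
      vals[, t, , ] <- array(pmax(vt, 0), c(nS, P, nF))
    }
    new("SpectralProfileSet",
        values = vals, freq = freq,
        subjectIds = subjectIds(design),
        sessionIds = sprintf("ses%02d", seq_len(nSessions)),
        meta = list(seed = seed, h2 = h2, c2 = c2,
                    sessionNoiseSd = truth@sessionNoiseSd,
                    bands = bandLimits(bands), generator = "simulateProfiles"))
  })
}

# 2 x nPairs matrix of subject indices, one column per twin pair.
pairIndexMatrix <- function(design, zygo = NULL) {
  pid <- pairIds(design)
  keep <- !is.na(pid)
  if (!is.null(zygo)) keep <- keep & zygosity(design) %in% zygo
  if (!any(keep)) return(matrix(integer(), 2L, 0L))
  sp <- split(which(keep), pid[keep])
  vapply(sp, identity, integer(2L))
}

#' Simulate donor-level parcellated gene expression
#'
#' Per-donor expression is the planted rank-1 signal
#' \code{geneWeights \%o\% latentMap} plus donor-specific noise with marginal
#' standard deviation \code{noiseSd}, a mixture of a spatially
#' autocorrelated Gaussian field (exponential kernel on centroid chord
#' distance, length \code{autocorrLength}) and white noise in proportion
#' \code{spatialFrac}. The donor average is returned together with per-gene
#' differential stability computed across donors.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nGenes number of genes (>= 2).
#' @param truth a [GroundTruth-class] with \code{geneWeights} of length
#'   \code{nGenes}.
#' @param autocorrLength spatial autocorrelation length on the unit sphere
#'   (chord distance; default 0.3, about one parcel neighbourhood for a
#'   200-parcel atlas). Must be positive.
#' @param noiseSd marginal noise standard deviation per donor (default 0.5;
#'   the planted per-gene signal has standard deviation |weight|).
#' @param spatialFrac fraction of the noise variance that is spatially
#'   autocorrelated (default 0.5).
#' @param nDonors number of donors averaged (default 6).
#' @param nNuisance number of nuisance expression gradients (default 8):
#'   donor-shared low-rank components (smooth cortical map x random gene
#'   weights) unrelated to the planted latent, emulating the many competing
#'   spatial gradients of real cortical transcriptomes.
#' @param nuisanceSd total marginal standard deviation of the nuisance
#'   gradients per gene (default 0.7, slightly below the typical planted
#'   per-gene signal).
#' @param seed integer seed.
#'
#' @return A [GeneExpressionMatrix-class] with populated stability values.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' truth <- makeGroundTruth(atlas, nGenes = 40, seed = 1)
#' simulateExpression(atlas, 40, truth, seed = 2)
#' @export
simulateExpression <- function(atlas, nGenes, truth, autocorrLength = 0.3,
                               noiseSd = 0.5, spatialFrac = 0.5,
                               nDonors = 6, nNuisance = 8, nuisanceSd = 0.7,
                               seed = 1) {
  stopifnot(is(atlas, "ParcelAtlas"), is(truth, "GroundTruth"))
  stopifnotScalarCount(nGenes, "nGenes", min = 2L)
  stopifnotScalarCount(nDonors, "nDonors", min = 1L)
  if (autocorrLength <= 0) {
    stop("'autocorrLength' must be positive", call. = FALSE)
  }
  if (length(truth@geneWeights) != nGenes) {
    stop("truth geneWeights length must equal nGenes", call. = FALSE)
  }
  P <- nParcels(atlas)
  withSeed(seed, {
    signal <- outer(truth@latentMap, truth@geneWeights)
    if (nNuisance > 0 && nuisanceSd > 0) {
      nMaps <- spatialField(centroids(atlas), nNuisance, ell = 0.4)
      nW <- matrix(stats::rnorm(nNuisance * nGenes), nNuisance)
      signal <- signal + (nuisanceSd / sqrt(nNuisance)) * nMaps %*% nW
    }
    donors <- vector("list", nDonors)
    for (d in seq_len(nDonors)) {
      sp <- spatialField(centroids(atlas), nGenes, ell = autocorrLength)
      wh <- matrix(stats::rnorm(P * nGenes), P)
      donors[[d]] <- signal +
        noiseSd * (sqrt(spatialFrac) * sp + sqrt(1 - spatialFrac) * wh)
    }
    ds <- differentialStability(donors)
    avg <- Reduce(`+`, donors) / nDonors
    new("GeneExpressionMatrix",
        values = avg,
        geneIds = sprintf("g%05d", seq_len(nGenes)),
        ds = as.numeric(ds),
        meta = list(seed = seed, nDonors = nDonors, noiseSd = noiseSd,
                    autocorrLength = autocorrLength,
                    spatialFrac = spatialFrac))
  })
}

#' Simulate cognitive-term activation maps
#'
#' Each term map loads on the planted latent gradient (half the terms
#' positively, half negatively) plus spatially smooth noise.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nTerms number of term maps (>= 2).
#' @param truth a [GroundTruth-class].
#' @param noiseSd smooth-noise standard deviation (default 0.3).
#' @param seed integer seed.
#'
#' @return parcels x terms numeric matrix with term-name columns and a
#'   \code{"plantedSign"} attribute (+1/-1 per term).
#' @examples
#' atlas <- makeAtlas(20, 1)
#' truth <- makeGroundTruth(atlas, 10, seed = 1)
#' tm <- simulateTermMaps(atlas, 4, truth, seed = 3)
#' cor(tm[, 1], truth@latentMap)
#' @export
simulateTermMaps <- function(atlas, nTerms, truth, noiseSd = 0.3, seed = 1) {
  stopifnot(is(atlas, "ParcelAtlas"), is(truth, "GroundTruth"))
  stopifnotScalarCount(nTerms, "nTerms", min = 2L)
  signs <- rep(c(1, -1), length.out = nTerms)
  withSeed(seed, {
    noise <- spatialField(centroids(atlas), nTerms, ell = 0.3)
    maps <- sweep(matrix(truth@latentMap, nParcels(atlas), nTerms), 2L,
                  signs, "*") + noiseSd * noise
    colnames(maps) <- sprintf("term%02d", seq_len(nTerms))
    attr(maps, "plantedSign") <- signs
    maps
  })
}

#' Simulate cell-type marker gene sets
#'
#' Builds disjoint marker sets for \code{nTypes} cell classes. The set named
#' by the planted enriched cell type is drawn preferentially (sampling weight
#' 2.25) from the top decile of the planted gene weights, so its overlap
#' with top-weight genes is about twice the background rate; all other sets
#' are uniform draws from the remaining pool.
#'
#' @param geneIds character vector of available gene labels (matched by
#'   position to \code{truth@geneWeights}).
#' @param nTypes number of cell classes (default 7: astrocytes, endothelial
#'   cells, microglia, excitatory neurons, inhibitory neurons,
#'   oligodendrocytes, OPCs).
#' @param truth a [GroundTruth-class].
#' @param setSize genes per set (default \code{max(5, round(0.05 * nGenes))}).
#' @param seed integer seed.
#'
#' @return Named list of disjoint character vectors (the cell-type
#'   annotation).
#' @examples
#' truth <- makeGroundTruth(makeAtlas(10, 1), nGenes = 200, seed = 1)
#' ann <- simulateCelltypeSets(sprintf("g%05d", 1:200), 7, truth, seed = 2)
#' lengths(ann)
#' @export
simulateCelltypeSets <- function(geneIds, nTypes = 7, truth, setSize = NULL,
                                 seed = 1) {
  stopifnot(is(truth, "GroundTruth"))
  stopifnotScalarCount(nTypes, "nTypes", min = 2L)
  nG <- length(geneIds)
  if (length(truth@geneWeights) != nG) {
    stop("geneIds must match truth geneWeights in length", call. = FALSE)
  }
  if (is.null(setSize)) setSize <- max(5L, round(0.05 * nG))
  if (nTypes * setSize > nG) {
    stop("requested sets exceed the gene pool", call. = FALSE)
  }
  labels <- if (nTypes == 7L) {
    c("astrocytes", "endothelial", "microglia", "excitatory", "inhibitory",
      "oligodendrocytes", "OPC")
  } else {
    sprintf("type%02d", seq_len(nTypes))
  }
  if (!truth@enrichedCelltype %in% labels) labels[1] <- truth@enrichedCelltype
  enrichedAt <- match(truth@enrichedCelltype, labels)
  topDecile <- truth@geneWeights >= stats::quantile(truth@geneWeights, 0.9)
  withSeed(seed, {
    w <- ifelse(topDecile, 2.25, 1)
    enriched <- sample(geneIds, setSize, prob = w)
    pool <- setdiff(geneIds, enriched)
    out <- vector("list", nTypes)
    out[[enrichedAt]] <- enriched
    for (k in setdiff(seq_len(nTypes), enrichedAt)) {
      out[[k]] <- sample(pool, setSize)
      pool <- setdiff(pool, out[[k]])
    }
    names(out) <- labels
    out
  })
}

#' Simulate developmental gene expression
#'
#' For every region except one designated null region, the projection of
#' expression onto the planted gene weights increases linearly across stage
#' index with slope \code{truth@devSlope}; the null region has slope zero
#' (emulating the hippocampal exception seen in developmental atlases).
#' Per-gene noise is scaled so the projected score noise has standard
#' deviation \code{scoreNoiseSd}.
#'
#' @param regions character vector of region labels (default 12 cortical
#'   regions plus the designated null region when absent).
#' @param stages number of developmental stages (>= 3).
#' @param geneIds character vector of gene labels matched to
#'   \code{truth@geneWeights}.
#' @param truth a [GroundTruth-class].
#' @param scoreNoiseSd noise standard deviation on the projected score scale
#'   (default 0.2).
#' @param nullRegion label of the zero-slope region (default
#'   \code{"hippocampus"} if present, else the last region).
#' @param seed integer seed.
#'
#' @return A [DevExpressionSet-class]; \code{meta} records the null region
#'   and planted slope.
#' @examples
#' truth <- makeGroundTruth(makeAtlas(10, 1), nGenes = 50, seed = 1)
#' dev <- simulateDevExpression(stages = 8, geneIds = sprintf("g%05d", 1:50),
#'                              truth = truth, seed = 4)
#' dev@regions
#' @export
simulateDevExpression <- function(regions = NULL, stages = 8,
                                  geneIds, truth, scoreNoiseSd = 0.2,
                                  nullRegion = NULL, seed = 1) {
  stopifnot(is(truth, "GroundTruth"))
  stopifnotScalarCount(stages, "stages", min = 3L)
  if (is.null(regions)) {
    regions <- c("DFC", "VFC", "OFC", "M1C", "S1C", "IPC", "A1C", "STC",
                 "ITC", "V1C", "MFC", "hippocampus")
  }
  if (is.null(nullRegion)) {
    nullRegion <- if ("hippocampus" %in% regions) "hippocampus" else
      regions[length(regions)]
  }
  if (!nullRegion %in% regions) {
    stop("'nullRegion' must be one of the regions", call. = FALSE)
  }
  nG <- length(geneIds)
  if (length(truth@geneWeights) != nG) {
    stop("geneIds must match truth geneWeights in length", call. = FALSE)
  }
  w <- truth@geneWeights
  wnorm2 <- sum(w^2)
  slopes <- ifelse(regions == nullRegion, 0, truth@devSlope)
  geneNoiseSd <- scoreNoiseSd / sqrt(wnorm2)
  withSeed(seed, {
    base <- stats::rnorm(nG)
    vals <- array(NA_real_, c(length(regions), stages, nG))
    for (r in seq_along(regions)) {
      for (s in seq_len(stages)) {
        vals[r, s, ] <- base + slopes[r] * s * w / wnorm2 +
          geneNoiseSd * stats::rnorm(nG)
      }
    }
    new("DevExpressionSet",
        values = vals, regions = regions,
        stages = seq_len(stages), geneIds = geneIds,
        meta = list(seed = seed, nullRegion = nullRegion,
                    devSlope = truth@devSlope, scoreNoiseSd = scoreNoiseSd))
  })
}

#' Simulate mock noise profiles (empty-room control)
#'
#' Emulates mock brain-fingerprints built from empty-room noise recordings:
#' a single session-varying set of noise source spectra, shared by all
#' subjects, is passed through a participant-specific random linear mixing
#' across parcels (standing in for projection onto individual cortical
#' source maps) and squared to a power-like quantity. The subject-specific
#' mixing is itself partly session-varying, so within-subject consistency is
#' far below that of [simulateProfiles()] output: differentiation from these
#' profiles can exceed the exact 1/N floor (the mixing leaks weak
#' participant-specific structure) but stays low.
#'
#' @param design a [CohortDesign-class].
#' @param atlas a [ParcelAtlas-class].
#' @param seed integer seed.
#' @param nSessions number of sessions (default 3).
#' @param freq frequency grid (default the 301-bin 0-150 Hz grid).
#' @param nSources number of shared noise sources (default 10).
#' @param mixInstability fraction (in sd) of each subject's mixing matrix
#'   redrawn per session (default 0.85, which leaves differentiation from
#'   mock profiles above the exact chance floor but an order of magnitude
#'   below planted-profile differentiation at study scale).
#'
#' @return A [SpectralProfileSet-class] of mock profiles.
#' @examples
#' mock <- simulateNoiseProfiles(makeCohort(0, 0, 6), makeAtlas(10, 1),
#'                               seed = 5)
#' mock
#' @export
simulateNoiseProfiles <- function(design, atlas, seed = 1, nSessions = 3,
                                  freq = seq(0, 150, by = 0.5),
                                  nSources = 10, mixInstability = 0.85) {
  stopifnot(is(design, "CohortDesign"), is(atlas, "ParcelAtlas"))
  nS <- nSubjects(design)
  P <- nParcels(atlas)
  nF <- length(freq)
  shape <- sqrt(baselineSpectrum(freq))
  withSeed(seed, {
    vals <- array(NA_real_, c(nS, nSessions, P, nF))
    stableMix <- lapply(seq_len(nS), function(i) {
      matrix(stats::rnorm(P * nSources), P)
    })
    for (t in seq_len(nSessions)) {
      src <- sweep(matrix(stats::rnorm(nSources * nF), nSources), 2L,
                   shape, "*")
      for (i in seq_len(nS)) {
        mix <- sqrt(1 - mixInstability^2) * stableMix[[i]] +
          mixInstability * matrix(stats::rnorm(P * nSources), P)
        vals[i, t, , ] <- (mix %*% src)^2
      }
    }
    new("SpectralProfileSet",
        values = vals, freq = freq,
        subjectIds = subjectIds(design),
        sessionIds = sprintf("ses%02d", seq_len(nSessions)),
        meta = list(seed = seed, generator = "simulateNoiseProfiles",
                    nSources = nSources, mixInstability = mixInstability))
  })
}
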