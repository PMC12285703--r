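# Generics and accessor methods; slots are never accessed directly by users.

#' @name accessors
#' @title Accessors for neuroprint classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object of the documented class.
#' @return The slot content named by the accessor.
#' @examples
#' atlas <- makeAtlas(10, seed = 1)
#' nParcels(atlas)
#' head(centroids(atlas))
NULL

#' @rdname accessors
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("nSessions", function(x) standardGeneric("nSessions"))
#' @rdname accessors
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @rdname accessors
#' @export
setGeneric("regionGroups", function(x) standardGeneric("regionGroups"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("sessionIds", function(x) standardGeneric("sessionIds"))
#' @rdname accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @rdname accessors
#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))
#' @rdname accessors
#' @export
setGeneric("freqGrid", function(x) standardGeneric("freqGrid"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("dsValues", function(x) standardGeneric("dsValues"))
#' @rdname accessors
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname accessors
#' @export
setGeneric("bandLimits", function(x) standardGeneric("bandLimits"))
#' @rdname accessors
#' @export
setGeneric("spinPermutations", function(x) standardGeneric("spinPermutations"))
#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("covExplained", function(x) standardGeneric("covExplained"))
#' @rdname accessors
#' @export
setGeneric("plsWeights", function(x) standardGeneric("plsWeights"))
#' @rdname accessors
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))
#' @rdname accessors
#' @export
setGeneric("plsLoadingValues", function(x) standardGeneric("plsLoadingValues"))
#' @rdname accessors
#' @export
setGeneric("metaData", function(x) standardGeneric("metaData"))

#' @rdname accessors
#' @export
setMethod("nParcels", "ParcelAtlas", function(x) length(x@parcelId))
#' @rdname accessors
#' @export
setMethod("parcelIds", "ParcelAtlas", function(x) x@parcelId)
#' @rdname accessors
#' @export
setMethod("centroids", "ParcelAtlas", function(x) x@centroid)
#' @rdname accessors
#' @export
setMethod("hemispheres", "ParcelAtlas", function(x) x@hemisphere)
#' @rdname accessors
#' @export
setMethod("regionGroups", "ParcelAtlas", function(x) x@regionGroup)

#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortDesign", function(x) length(x@subjectId))
#' @rdname accessors
#' @export
setMethod("subjectIds", "CohortDesign", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("pairIds", "CohortDesign", function(x) x@pairId)
#' @rdname accessors
#' @export
setMethod("zygosity", "CohortDesign", function(x) x@zygosity)

#' @rdname accessors
#' @export
setMethod("nSubjects", "SpectralProfileSet", function(x) dim(x@values)[1])
#' @rdname accessors
#' @export
setMethod("nSessions", "SpectralProfileSet", function(x) dim(x@values)[2])
#' @rdname accessors
#' @export
setMethod("nParcels", "SpectralProfileSet", function(x) dim(x@values)[3])
#' @rdname accessors
#' @export
setMethod("subjectIds", "SpectralProfileSet", function(x) x@subjectIds)
#' @rdname accessors
#' @export
setMethod("sessionIds", "SpectralProfileSet", function(x) x@sessionIds)
#' @rdname accessors
#' @export
setMethod("freqGrid", "SpectralProfileSet", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("profileValues", "SpectralProfileSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("metaData", "SpectralProfileSet", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("nParcels", "GeneExpressionMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneExpressionMatrix", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("exprValues", "GeneExpressionMatrix", function(x) {
  v <- x@values
  colnames(v) <- x@geneIds
  v
})
#' @rdname accessors
#' @export
setMethod("dsValues", "GeneExpressionMatrix", function(x) {
  stats::setNames(x@ds, x@geneIds)
})
#' @rdname accessors
#' @export
setMethod("metaData", "GeneExpressionMatrix", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("bandNames", "BandScheme", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("bandLimits", "BandScheme", function(x) {
  data.frame(name = x@name, lo = x@lo, hi = x@hi)
})

#' @rdname accessors
#' @export
setMethod("spinPermutations", "SpinNull", function(x) x@permutations)

#' @rdname accessors
#' @export
setMethod("singularValues", "PLSModel", function(x) x@s)
#' @rdname accessors
#' @export
setMethod("covExplained", "PLSModel", function(x) x@covExplained)
#' @rdname accessors
#' @export
setMethod("plsWeights", "PLSModel", function(x) list(x = x@u, y = x@v))
#' @rdname accessors
#' @export
setMethod("plsScores", "PLSModel", function(x) list(x = x@xScores, y = x@yScores))
#' @rdname accessors
#' @export
setMethod("plsLoadingValues", "PLSModel", function(x) {
  list(x = x@xLoadings, y = x@yLoadings)
})
#' @rdname accessors
#' @export
setMethod("metaData", "PLSModel", function(x) x@meta)

setMethod("show", "ParcelAtlas", function(object) {
  cat("ParcelAtlas with", nParcels(object), "parcels (",
      sum(object@hemisphere == "L"), "L /",
      sum(object@hemisphere == "R"), "R )\n")
})

setMethod("show", "CohortDesign", function(object) {
  z <- object@zygosity
  cat("CohortDesign:", length(object@subjectId), "subjects |",
      sum(z == "MZ") / 2, "MZ pairs,", sum(z == "DZ") / 2, "DZ pairs,",
      sum(z == "UNRELATED"), "unrelated\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: h2 = %.2f, c2 = %.2f, sessionNoiseSd = %.2f, devSlope = %.2f\n",
    object@h2, object@c2, object@sessionNoiseSd, object@devSlope))
  cat("  latentMap:", length(object@latentMap), "parcels; geneWeights:",
      length(object@geneWeights), "genes; enriched cell type:",
      object@enrichedCelltype, "\n")
})

setMethod("show", "BandScheme", function(object) {
  cat("BandScheme with", length(object@name), "bands:\n")
  for (i in seq_along(object@name)) {
    cat(sprintf("  %-10s %5.1f - %5.1f Hz\n",
                object@name[i], object@lo[i], object@hi[i]))
  }
})

setMethod("show", "SpectralProfileSet", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "SpectralProfileSet: %d subjects x %d sessions x %d parcels x %d bins (%g-%g Hz)\n",
    d[1], d[2], d[3], d[4], min(object@freq), max(object@freq)))
})

setMethod("show", "GeneExpressionMatrix", function(object) {
  cat("GeneExpressionMatrix:", nrow(object@values), "parcels x",
      ncol(object@values), "genes; median DS =",
      round(stats::median(object@ds, na.rm = TRUE), 3), "\n")
})

setMethod("show", "SpinNull", function(object) {
  cat("SpinNull:", nrow(object@permutations), "spatial permutations of",
      ncol(object@permutations), "parcels (seed", object@seed, ")\n")
})

setMethod("show", "PLSModel", function(object) {
  k <- length(object@s)
  cat("PLSModel with", k, "components\n")
  cat("  covariance explained:",
      paste(sprintf("%.3f", object@covExplained[seq_len(min(k, 4))]),
            collapse = ", "),
      if (k > 4) "...\n" else "\n")
  if (length(object@pSpin)) {
    cat("  spin p (comp 1):", signif(object@pSpin[1], 3), "\n")
  }
})
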