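# Configuration-driven end-to-end run: simulate -> fingerprint ->
# heritability -> spins -> pls -> association, with a reproducibility
# manifest.

pipelineDefaults <- function() {
  list(
    outDir = "neuroprint_run",
    seed = 1L,
    stages = c("simulate", "fingerprint", "heritability", "spins", "pls",
               "association"),
    nParcels = 100L,
    nMzPairs = 17L, nDzPairs = 11L, nUnrelated = 33L,
    nSessions = 3L,
    nGenes = 300L,
    h2 = 0.6, c2 = 0.1, sessionNoiseSd = 0.3,
    nSubsamples = 100L,
    nPermHeritability = 200L,
    nSpins = 200L,
    nBoot = 200L,
    nCvRep = 100L, nCvNullSpin = 50L,
    nPermEnrich = 500L,
    devStages = 8L,
    bands = NULL,            # NULL -> defaultBands()
    profilesDir = NULL       # read profiles instead of simulating
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order on simulated (or previously
#' saved) data, writes every stage artifact plus a manifest (package
#' version, seeds, input digests, per-stage timing) under
#' \code{config$outDir}, and returns the stage results. Identical
#' configurations produce identical numeric outputs. Unknown configuration
#' keys are rejected.
#'
#' @param config named list, or path to a JSON file holding one; see
#'   the vignette for the key set and defaults. Unknown keys are an error.
#'
#' @return Invisibly, a list with one entry per executed stage plus
#'   \code{manifest}.
#' @examples
#' \donttest{
#' cfg <- list(outDir = tempfile(), nParcels = 20, nMzPairs = 4,
#'             nDzPairs = 4, nUnrelated = 4, nGenes = 60, nSpins = 20,
#'             nSubsamples = 10, nPermHeritability = 20, nBoot = 20,
#'             nCvRep = 10, nCvNullSpin = 5, nPermEnrich = 50)
#' rep <- runPipeline(cfg)
#' names(rep)
#' }
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  bands <- if (is.null(cfg$bands)) defaultBands() else
    bandScheme(cfg$bands$name, cfg$bands$lo, cfg$bands$hi)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  manifest <- list(package = "neuroprint",
                   version = as.character(utils::packageVersion("neuroprint")),
                   seed = cfg$seed, stages = list(), files = list())
  tic <- function() proc.time()[["elapsed"]]
  stageDone <- function(name, t0) {
    manifest$stages[[name]] <<- list(seconds = round(tic() - t0, 2),
                                     seed = childSeed(cfg$seed, match(name, cfg$stages)))
  }

  atlas <- makeAtlas(cfg$nParcels, seed = childSeed(cfg$seed, 1L))
  design <- makeCohort(cfg$nMzPairs, cfg$nDzPairs, cfg$nUnrelated)
  truth <- makeGroundTruth(atlas, nGenes = cfg$nGenes, h2 = cfg$h2,
                           c2 = cfg$c2, sessionNoiseSd = cfg$sessionNoiseSd,
                           seed = childSeed(cfg$seed, 2L))

  profiles <- NULL
  if ("simulate" %in% cfg$stages) {
    t0 <- tic()
    if (!is.null(cfg$profilesDir)) {
      profiles <- readProfiles(cfg$profilesDir)
    } else {
      profiles <- simulateProfiles(design, atlas, bands, truth,
                                   nSessions = cfg$nSessions,
                                   seed = childSeed(cfg$seed, 3L))
    }
    writeAtlas(atlas, file.path(cfg$outDir, "atlas.csv"))
    writeCohort(design, file.path(cfg$outDir, "cohort.csv"))
    report$simulate <- list(nSubjects = nSubjects(profiles),
                            nParcels = nParcels(profiles))
    stageDone("simulate", t0)
  }

  needProfiles <- function() {
    if (is.null(profiles)) stop("stage requires the simulate stage",
                                call. = FALSE)
    profiles
  }

  if ("fingerprint" %in% cfg$stages) {
    t0 <- tic()
    p <- needProfiles()
    fp <- differentiationAccuracy(p)
    mz <- if (cfg$nMzPairs >= 1) twinMatchingAccuracy(p, design, "MZ") else NULL
    dz <- if (cfg$nDzPairs >= 1) twinMatchingAccuracy(p, design, "DZ") else NULL
    rnd <- if (cfg$nUnrelated >= 4) {
      randomPairMatching(p, design, nIter = 100,
                         seed = childSeed(cfg$seed, 4L))
    } else NULL
    report$fingerprint <- list(
      accuracy = fp$accuracy,
      mzMatching = if (!is.null(mz)) mz$accuracy else NA_real_,
      dzMatching = if (!is.null(dz)) dz$accuracy else NA_real_,
      randomMatching = if (!is.null(rnd)) rnd$accuracy else NA_real_)
    jsonlite::write_json(report$fingerprint,
                         file.path(cfg$outDir, "fingerprint.json"),
                         auto_unbox = TRUE, digits = NA)
    stageDone("fingerprint", t0)
  }

  iccMap <- NULL
  if ("heritability" %in% cfg$stages) {
    t0 <- tic()
    p <- needProfiles()
    iccMap <- saliencyMap(p, design, bands, nSubsamples = cfg$nSubsamples,
                          seed = childSeed(cfg$seed, 5L))
    hm <- heritabilityMap(p, design, bands, nPerm = cfg$nPermHeritability,
                          seed = childSeed(cfg$seed, 6L))
    tab <- data.frame(
      parcel = rep(seq_len(nrow(hm$h2)), times = ncol(hm$h2)),
      band = rep(hm$bands, each = nrow(hm$h2)),
      icc = as.vector(iccMap$subsampleMean),
      r_mz = as.vector(hm$rMz), r_dz = as.vector(hm$rDz),
      h2 = as.vector(hm$h2), h2_raw = as.vector(hm$h2Raw),
      p = as.vector(hm$pPerm), q = as.vector(hm$qFdr))
    utils::write.table(tab, file.path(cfg$outDir, "heritability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$heritability <- list(meanH2 = mean(hm$h2, na.rm = TRUE),
                                map = hm, icc = iccMap)
    stageDone("heritability", t0)
  }

  spins <- NULL
  if ("spins" %in% cfg$stages) {
    t0 <- tic()
    spins <- generateSpins(atlas, nPerm = cfg$nSpins,
                           seed = childSeed(cfg$seed, 7L))
    writeSpins(spins, file.path(cfg$outDir, "spins.csv"))
    report$spins <- list(nPerm = cfg$nSpins)
    stageDone("spins", t0)
  }

  expr <- NULL; model <- NULL
  if ("pls" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(iccMap) || is.null(spins)) {
      stop("pls stage requires heritability and spins stages", call. = FALSE)
    }
    expr <- simulateExpression(atlas, cfg$nGenes, truth,
                               seed = childSeed(cfg$seed, 8L))
    expr <- filterByDS(expr)
    writeExpression(expr, file.path(cfg$outDir, "expression.tsv"))
    Y <- iccMap$subsampleMean
    colnames(Y) <- iccMap$bands
    model <- fitPLS(expr, Y)
    model <- plsSignificance(expr, Y, spins, model = model)
    model <- plsBootstrap(expr, Y, nBoot = cfg$nBoot,
                          seed = childSeed(cfg$seed, 9L), model = model)
    model <- plsLoadings(model, expr, Y)
    cv <- distanceSplitCV(expr, Y, atlas, nRep = cfg$nCvRep, null = spins,
                          nNullSpin = cfg$nCvNullSpin,
                          seed = childSeed(cfg$seed, 10L))
    modelJson <- list(
      s = model@s, covExplained = model@covExplained, pSpin = model@pSpin,
      bootCI = model@bootCI, u = model@u, v = model@v,
      xScores = model@xScores, yScores = model@yScores,
      cvMedianR = cv$medianR, cvPSpin = cv$pSpin)
    jsonlite::write_json(modelJson, file.path(cfg$outDir, "pls_model.json"),
                         digits = NA)
    report$pls <- list(model = model, cv = cv)
    stageDone("pls", t0)
  }

  if ("association" %in% cfg$stages) {
    t0 <- tic()
    if (is.null(model)) stop("association stage requires the pls stage",
                             call. = FALSE)
    keptIdx <- match(geneIds(expr), sprintf("g%05d", seq_len(cfg$nGenes)))
    keptTruth <- new("GroundTruth", h2 = truth@h2, c2 = truth@c2,
                     sessionNoiseSd = truth@sessionNoiseSd,
                     latentMap = truth@latentMap,
                     geneWeights = truth@geneWeights[keptIdx],
                     bandWeights = truth@bandWeights,
                     enrichedCelltype = truth@enrichedCelltype,
                     devSlope = truth@devSlope)
    ann <- simulateCelltypeSets(geneIds(expr), 7, keptTruth,
                                seed = childSeed(cfg$seed, 11L))
    writeGmt(ann, file.path(cfg$outDir, "celltypes.gmt"))
    pos <- selectLoadedGenes(model, "positive")
    enr <- celltypeEnrichment(pos, ann, geneIds(expr),
                              nPerm = cfg$nPermEnrich,
                              seed = childSeed(cfg$seed, 12L))
    utils::write.table(enr, file.path(cfg$outDir, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dev <- simulateDevExpression(stages = cfg$devStages,
                                 geneIds = geneIds(expr),
                                 truth = keptTruth,
                                 seed = childSeed(cfg$seed, 13L))
    writeDevExpression(dev, file.path(cfg$outDir, "dev_expression.tsv"))
    Y <- iccMap$subsampleMean
    colnames(Y) <- iccMap$bands
    slopes <- slopePermutationTest(expr, Y, dev, spins)
    utils::write.table(slopes, file.path(cfg$outDir, "dev_slopes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$association <- list(enrichment = enr, slopes = slopes)
    stageDone("association", t0)
  }

  outFiles <- list.files(cfg$outDir, recursive = TRUE, full.names = TRUE)
  outFiles <- setdiff(outFiles, file.path(cfg$outDir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(outFiles))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$manifest <- manifest
  invisible(report)
}
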