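# Downstream analyses of a fitted PLS model: loaded-gene selection,
# cell-type gene-set permutation enrichment, developmental gene-score
# trajectories with spin-nulled slopes.

#' Select strongly loaded genes from a PLS model
#'
#' Among genes whose component loading has the requested sign, returns the
#' \code{fraction} with the largest absolute loadings (default the 50\%
#' most positive or most negative).
#'
#' @param model a [PLSModel-class] with gene loadings (see [plsLoadings()]).
#' @param sign \code{"positive"} or \code{"negative"}.
#' @param fraction fraction of same-sign genes to keep, in (0, 1]
#'   (default 0.5); the kept count is \code{ceiling(fraction * n)}.
#' @param component component index (default 1).
#'
#' @return Character vector of gene ids.
#' @examples
#' X <- matrix(rnorm(400), 20, 20); colnames(X) <- paste0("g", 1:20)
#' Y <- matrix(rnorm(80), 20)
#' m <- plsLoadings(fitPLS(X, Y), X, Y)
#' length(selectLoadedGenes(m, "positive"))
#' @export
selectLoadedGenes <- function(model, sign = c("positive", "negative"),
                              fraction = 0.5, component = 1) {
  sign <- match.arg(sign)
  if (fraction <= 0 || fraction > 1) {
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (!nrow(model@xLoadings)) {
    stop("model has no gene loadings; run plsLoadings() first", call. = FALSE)
  }
  ld <- model@xLoadings[, component]
  ids <- model@meta$xIds
  sel <- if (sign == "positive") which(ld > 0) else which(ld < 0)
  if (!length(sel)) {
    stop("no genes with ", sign, " loadings", call. = FALSE)
  }
  nKeep <- ceiling(fraction * length(sel))
  ids[sel[order(abs(ld[sel]), decreasing = TRUE)][seq_len(nKeep)]]
}

#' Cell-type gene-set permutation enrichment
#'
#' For each cell-type marker set, the observed statistic is the fraction of
#' the query gene set overlapping that marker set. The null draws
#' size-matched random gene sets from the background \code{nPerm} times
#' (default 1000); two-tailed p-values are twice the smaller tail
#' probability (capped at 1, +1 correction) and BH-FDR adjusted across cell
#' types.
#'
#' @param geneSet character vector of query genes (must be contained in
#'   \code{background}).
#' @param annotation named list of cell-type marker gene sets.
#' @param background character vector of all eligible genes (e.g. all genes
#'   that entered the PLS after the stability filter).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#'
#' @return data.frame of class \code{"EnrichmentResult"}: one row per cell
#'   type with \code{ratio}, \code{nullMean}, \code{p}, \code{q},
#'   \code{direction} (\code{"over"}/\code{"under"}).
#' @examples
#' bg <- paste0("g", 1:100)
#' ann <- list(a = bg[1:10], b = bg[11:30])
#' celltypeEnrichment(bg[1:12], ann, bg, nPerm = 99, seed = 1)
#' @export
celltypeEnrichment <- function(geneSet, annotation, background, nPerm = 1000,
                               seed = 1) {
  if (!all(geneSet %in% background)) {
    stop("geneSet must be a subset of background", call. = FALSE)
  }
  if (length(background) < length(geneSet)) {
    stop("background smaller than geneSet", call. = FALSE)
  }
  nTypes <- length(annotation)
  m <- length(geneSet)
  obs <- vapply(annotation, function(set) {
    sum(geneSet %in% set) / m
  }, numeric(1))
  inSet <- vapply(annotation, function(set) background %in% set,
                  logical(length(background)))  # |bg| x types
  nullRatios <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(k) {
      draw <- sample.int(length(background), m)
      colSums(inSet[draw, , drop = FALSE]) / m
    }, numeric(nTypes)))
  })
  pHi <- (1 + colSums(nullRatios >= rep(obs, each = nPerm))) / (1 + nPerm)
  pLo <- (1 + colSums(nullRatios <= rep(obs, each = nPerm))) / (1 + nPerm)
  p <- pmin(1, 2 * pmin(pHi, pLo))
  nullMean <- colMeans(nullRatios)
  out <- data.frame(
    cellType = names(annotation),
    ratio = unname(obs),
    nullMean = unname(nullMean),
    p = unname(p),
    q = bhFdr(unname(p)),
    direction = ifelse(obs >= nullMean, "over", "under"),
    row.names = NULL
  )
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone and bounded by 1.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#'
#' @return Adjusted values, same length.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues <= 0) || any(pValues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pValues, method = "BH")
}

#' Developmental gene scores
#'
#' Projects a developmental expression set onto a gene-weight vector (e.g. a
#' PLS component-1 gene weight vector): the score of a region at a stage is
#' the inner product of its expression with the weights over the shared
#' genes. Genes absent from either side are dropped, with the count
#' recorded in the \code{"nDropped"} attribute.
#'
#' @param dev a [DevExpressionSet-class].
#' @param geneWeights named numeric vector of gene weights (>= 2 genes must
#'   overlap the developmental set).
#'
#' @return regions x stages numeric matrix of scores.
#' @examples
#' truth <- makeGroundTruth(makeAtlas(10, 1), 30, seed = 1)
#' ids <- sprintf("g%05d", 1:30)
#' dev <- simulateDevExpression(stages = 6, geneIds = ids, truth = truth)
#' sc <- devGeneScores(dev, stats::setNames(truth@geneWeights, ids))
#' dim(sc)
#' @export
devGeneScores <- function(dev, geneWeights) {
  stopifnot(is(dev, "DevExpressionSet"))
  if (is.null(names(geneWeights))) {
    stop("geneWeights must be named by gene id", call. = FALSE)
  }
  shared <- intersect(dev@geneIds, names(geneWeights))
  if (length(shared) < 2L) {
    stop("fewer than 2 genes shared between weights and the developmental set",
         call. = FALSE)
  }
  gi <- match(shared, dev@geneIds)
  w <- geneWeights[shared]
  nR <- length(dev@regions); nS <- length(dev@stages)
  flat <- matrix(dev@values[, , gi, drop = FALSE], nR * nS, length(gi))
  scores <- matrix(flat %*% w, nR, nS,
                   dimnames = list(dev@regions, dev@stages))
  attr(scores, "nDropped") <- length(dev@geneIds) - length(shared) +
    length(geneWeights) - length(shared)
  scores
}

#' Per-region developmental slopes
#'
#' Ordinary least-squares slope of the gene score against the integer stage
#' index, fitted per region.
#'
#' @param scores regions x stages matrix (>= 3 stages), e.g. from
#'   [devGeneScores()].
#'
#' @return Named numeric vector of slopes.
#' @examples
#' stageSlopes(rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2)))
#' @export
stageSlopes <- function(scores) {
  scores <- as.matrix(scores)
  nS <- ncol(scores)
  if (nS < 3L) stop("need >= 3 stages", call. = FALSE)
  s <- seq_len(nS)
  sc <- s - mean(s)
  drop(scores %*% sc) / sum(sc^2)
}

#' Spin-nulled developmental slope test
#'
#' Fits the PLS model on \code{X}, \code{Y}, projects the developmental
#' expression onto the component-1 gene weights and fits per-region slopes;
#' the null refits the PLS on spin-permuted \code{Y} per spin, derives null
#' gene weights and recomputes the slopes. One-tailed p-values (slope at
#' least as large as the null, +1 correction) are BH-FDR adjusted across
#' regions; a two-tailed variant is available by flag.
#'
#' @param X gene expression (parcels x genes with gene-id columns).
#' @param Y trait maps (parcels x bands).
#' @param dev a [DevExpressionSet-class].
#' @param null a [SpinNull-class].
#' @param nPerm number of spins used (default: all rows of \code{null}).
#' @param twoTailed use a two-tailed p-value (default FALSE, matching the
#'   directional "strengthens across development" hypothesis).
#'
#' @return data.frame: region, slope, p, q.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' truth <- makeGroundTruth(atlas, 40, seed = 1)
#' X <- simulateExpression(atlas, 40, truth, seed = 2)
#' Y <- matrix(truth@latentMap + rnorm(20, sd = 0.3), 20, 2)
#' dev <- simulateDevExpression(stages = 6, geneIds = geneIds(X), truth = truth)
#' spins <- generateSpins(atlas, 49, seed = 3)
#' slopePermutationTest(X, Y, dev, spins)[1:3, ]
#' @export
slopePermutationTest <- function(X, Y, dev, null, nPerm = NULL,
                                 twoTailed = FALSE) {
  stopifnot(is(dev, "DevExpressionSet"), is(null, "SpinNull"))
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  if (is.null(nPerm)) nPerm <- nrow(null@permutations)
  nPerm <- min(nPerm, nrow(null@permutations))
  zx <- zscoreColumns(Xm, "X"); zy <- zscoreColumns(Ym, "Y")
  slopesFromU <- function(u1) {
    w <- stats::setNames(u1, colnames(Xm))
    stageSlopes(devGeneScores(dev, w))
  }
  obs <- slopesFromU(plsCore(zx$z, zy$z)$u[, 1L])
  nR <- length(obs)
  geCount <- numeric(nR); absGeCount <- numeric(nR)
  for (k in seq_len(nPerm)) {
    Yp <- zy$z[null@permutations[k, ], , drop = FALSE]
    nullSl <- slopesFromU(plsCore(zx$z, Yp)$u[, 1L])
    geCount <- geCount + (nullSl >= obs)
    absGeCount <- absGeCount + (abs(nullSl) >= abs(obs))
  }
  p <- if (twoTailed) (1 + absGeCount) / (1 + nPerm) else
    (1 + geCount) / (1 + nPerm)
  data.frame(region = names(obs), slope = unname(obs), p = unname(p),
             q = bhFdr(unname(p)), row.names = NULL)
}
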