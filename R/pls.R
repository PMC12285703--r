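# PLS correlation (PLS-SVD) between two parcel-indexed matrices, with spin
# significance, bootstrap, correlation loadings, distance-based
# cross-validation and cross-model alignment.

# Accept a FeatureMap-like input: plain matrix (parcels x variables) or a
# GeneExpressionMatrix.
asFeatureMatrix <- function(x, what = "X") {
  if (is(x, "GeneExpressionMatrix")) return(exprValues(x))
  if (is(x, "ICCMap")) stop("pass the ICC matrix, e.g. x$subsampleMean",
                            call. = FALSE)
  m <- as.matrix(x)
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("%s%03d", tolower(what), seq_len(ncol(m)))
  }
  m
}

zscoreColumns <- function(m, what) {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0)) {
    stop(sprintf("zero-variance column(s) in %s: %s", what,
                 paste(colnames(m)[sdv == 0], collapse = ", ")),
         call. = FALSE)
  }
  list(z = sweep(sweep(m, 2L, mu), 2L, sdv, "/"), mu = mu, sd = sdv)
}

# Core decomposition used by fit, permutation and CV paths.
plsCore <- function(Xz, Yz) {
  C <- crossprod(Xz, Yz) / (nrow(Xz) - 1)
  sv <- svd(C)
  k <- min(dim(C))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # joint sign convention: net-positive Y weighting (sum of v >= 0); on a
  # zero sum, largest-|.| element of v positive. Score covariances are
  # non-negative automatically (they equal the singular values).
  for (j in seq_len(k)) {
    sj <- sum(v[, j])
    if (sj == 0) sj <- v[which.max(abs(v[, j])), j]
    if (sj < 0) {
      v[, j] <- -v[, j]; u[, j] <- -u[, j]
    }
  }
  list(u = u, v = v, s = sv$d[seq_len(k)])
}

#' Fit a PLS correlation model
#'
#' Columns of both matrices are z-scored; the cross-covariance matrix
#' \eqn{X_z^\top Y_z / (n - 1)} is decomposed by SVD into paired weight
#' vectors (saliences) and singular values. Scores are the z-scored data
#' projected onto the weights; by construction each component's x/y score
#' covariance equals its singular value, hence is non-negative. The residual
#' joint sign indeterminacy is fixed by making the largest-magnitude entry
#' of each Y-weight vector positive.
#'
#' @param X parcels x variables matrix (or [GeneExpressionMatrix-class]),
#'   e.g. gene expression.
#' @param Y parcels x variables matrix, e.g. band-wise ICC values. Same
#'   parcel count as \code{X}; >= 3 parcels; no zero-variance columns.
#'
#' @return A [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(200), 20); Y <- matrix(rnorm(80), 20)
#' fitPLS(X, Y)
#' @export
fitPLS <- function(X, Y) {
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  if (nrow(Xm) != nrow(Ym)) stop("parcel counts differ", call. = FALSE)
  if (nrow(Xm) < 3L) stop("need >= 3 parcels", call. = FALSE)
  zx <- zscoreColumns(Xm, "X"); zy <- zscoreColumns(Ym, "Y")
  core <- plsCore(zx$z, zy$z)
  xs <- zx$z %*% core$u
  ys <- zy$z %*% core$v
  new("PLSModel",
      u = core$u, v = core$v, s = core$s,
      covExplained = core$s^2 / sum(core$s^2),
      xScores = xs, yScores = ys,
      xLoadings = matrix(numeric(), 0L, 0L),
      yLoadings = matrix(numeric(), 0L, 0L),
      pSpin = numeric(), bootCI = matrix(numeric(), 0L, 0L),
      meta = list(xIds = colnames(Xm), yIds = colnames(Ym),
                  xMeans = zx$mu, xSds = zx$sd,
                  yMeans = zy$mu, ySds = zy$sd,
                  nParcels = nrow(Xm)))
}

#' Spin-test significance of PLS components
#'
#' Refits the model with the rows of \code{Y} permuted by each spatial spin
#' and compares the empirical singular values to the null singular values,
#' component-wise: \eqn{p_k = (1 + \#\{s^{null}_k \ge s_k\}) / (1 + n)}.
#'
#' @param X,Y as in [fitPLS()].
#' @param null a [SpinNull-class] on the same parcels.
#' @param model optional prefit [PLSModel-class] for \code{X}, \code{Y}.
#'
#' @return The [PLSModel-class] with its spin p-values filled in; the null
#'   singular values are stored in \code{metaData(model)$nullS}.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' X <- matrix(rnorm(200), 20); Y <- matrix(rnorm(80), 20)
#' m <- plsSignificance(X, Y, generateSpins(atlas, 49, seed = 2))
#' metaData(m)$nullS[1:3, 1]
#' @export
plsSignificance <- function(X, Y, null, model = NULL) {
  stopifnot(is(null, "SpinNull"))
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  if (is.null(model)) model <- fitPLS(Xm, Ym)
  zx <- zscoreColumns(Xm, "X"); zy <- zscoreColumns(Ym, "Y")
  nPerm <- nrow(null@permutations)
  k <- length(model@s)
  nullS <- matrix(NA_real_, nPerm, k)
  for (p in seq_len(nPerm)) {
    Yp <- zy$z[null@permutations[p, ], , drop = FALSE]
    C <- crossprod(zx$z, Yp) / (nrow(zx$z) - 1)
    nullS[p, ] <- svd(C, nu = 0, nv = 0)$d[seq_len(k)]
  }
  pv <- vapply(seq_len(k), function(j) {
    permPvalue(nullS[, j], model@s[j], "greater")
  }, numeric(1))
  model@pSpin <- pv
  model@meta$nullS <- nullS
  model
}

#' Bootstrap confidence intervals for covariance explained
#'
#' Jointly resamples the parcels (rows of both matrices) with replacement
#' \code{nBoot} times and reports the percentile 95\% interval of the
#' covariance-explained fraction per component. Degenerate resamples (any
#' constant column) are skipped and counted.
#'
#' @param X,Y as in [fitPLS()] (>= 10 parcels).
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param model optional prefit [PLSModel-class].
#'
#' @return The [PLSModel-class] with \code{bootCI} filled (components x 2);
#'   skipped-resample count in \code{metaData(model)$bootSkipped}.
#' @examples
#' X <- matrix(rnorm(300), 30); Y <- matrix(rnorm(120), 30)
#' m <- plsBootstrap(X, Y, nBoot = 50, seed = 1)
#' m@bootCI[1, ]
#' @export
plsBootstrap <- function(X, Y, nBoot = 1000, seed = 1, model = NULL) {
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  if (nrow(Xm) < 10L) stop("need >= 10 parcels", call. = FALSE)
  if (is.null(model)) model <- fitPLS(Xm, Ym)
  k <- length(model@s)
  n <- nrow(Xm)
  withSeed(seed, {
    ce <- matrix(NA_real_, nBoot, k)
    skipped <- 0L
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- Xm[idx, , drop = FALSE]; Yb <- Ym[idx, , drop = FALSE]
      if (any(apply(Xb, 2L, stats::sd) == 0) ||
          any(apply(Yb, 2L, stats::sd) == 0)) {
        skipped <- skipped + 1L
        next
      }
      s <- plsCore(zscoreColumns(Xb, "X")$z, zscoreColumns(Yb, "Y")$z)$s
      ce[b, ] <- s^2 / sum(s^2)
    }
    ok <- stats::complete.cases(ce)
    if (!any(ok)) stop("all bootstrap resamples degenerate", call. = FALSE)
    ci <- t(apply(ce[ok, , drop = FALSE], 2L, stats::quantile,
                  probs = c(0.025, 0.975)))
    model@bootCI <- unname(ci)
    model@meta$bootSkipped <- skipped
    model
  })
}

#' Correlation loadings of PLS variables
#'
#' The loading of a variable is the Pearson correlation between that
#' variable's parcel vector and the opposite block's score pattern for the
#' component (e.g. a band's ICC map against the gene score pattern), so
#' loadings are bounded in [-1, 1]. Constant variables get \code{NA},
#' flagged in \code{metaData(model)$undefinedLoadings}.
#'
#' @param model a fitted [PLSModel-class].
#' @param X,Y the matrices the model was fitted on.
#'
#' @return The [PLSModel-class] with \code{xLoadings} / \code{yLoadings}
#'   filled (variables x components).
#' @examples
#' X <- matrix(rnorm(200), 20); Y <- matrix(rnorm(80), 20)
#' m <- plsLoadings(fitPLS(X, Y), X, Y)
#' range(m@yLoadings)
#' @export
plsLoadings <- function(model, X, Y) {
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  xl <- suppressWarnings(stats::cor(Xm, model@yScores))
  yl <- suppressWarnings(stats::cor(Ym, model@xScores))
  und <- list(x = which(apply(Xm, 2L, stats::sd) == 0),
              y = which(apply(Ym, 2L, stats::sd) == 0))
  model@xLoadings <- xl
  model@yLoadings <- yl
  if (length(und$x) || length(und$y)) model@meta$undefinedLoadings <- und
  model
}

#' Distance-based split cross-validation of the first PLS component
#'
#' Per repetition, a random seed parcel is drawn; the training set is the
#' \code{trainFrac} fraction of parcels nearest to it in centroid Euclidean
#' distance, the test set the remainder. Z-scoring parameters and
#' component-1 weights are estimated on the training parcels only; held-out
#' parcels are projected and the out-of-sample correlation between their x-
#' and y-scores recorded. The statistic is the median over repetitions;
#' significance compares it to medians obtained by re-running the whole
#' procedure on spin-permuted \code{Y} (one-tailed).
#'
#' @param X,Y as in [fitPLS()].
#' @param atlas a [ParcelAtlas-class] for parcel distances.
#' @param trainFrac training fraction in (0.5, 0.95); default 0.75.
#' @param nRep number of random splits (default 1000).
#' @param null optional [SpinNull-class] used for the significance null.
#' @param nNullSpin number of spins used for the null (default
#'   \code{min(100, available spins)}).
#' @param seed integer seed.
#'
#' @return List: \code{medianR}, \code{oosR} (per repetition), \code{pSpin}
#'   (\code{NA} without a null), \code{nullMedians}, \code{nSkipped}.
#' @examples
#' atlas <- makeAtlas(30, 1)
#' X <- matrix(rnorm(600), 30); Y <- X[, 1:3] + 0.1 * matrix(rnorm(90), 30)
#' distanceSplitCV(X, Y, atlas, nRep = 20, seed = 2)$medianR
#' @export
distanceSplitCV <- function(X, Y, atlas, trainFrac = 0.75, nRep = 1000,
                            null = NULL, nNullSpin = 100, seed = 1) {
  if (trainFrac <= 0.5 || trainFrac >= 0.95) {
    stop("'trainFrac' must lie in (0.5, 0.95)", call. = FALSE)
  }
  Xm <- asFeatureMatrix(X, "X"); Ym <- asFeatureMatrix(Y, "Y")
  P <- nrow(Xm)
  stopifnot(nParcels(atlas) == P)
  cen <- centroids(atlas)
  D <- as.matrix(stats::dist(cen))
  nTrain <- ceiling(trainFrac * P)

  oneCV <- function(Ymat, seeds) {
    vapply(seq_along(seeds), function(r) {
      anchor <- seeds[r]
      train <- order(D[anchor, ])[seq_len(nTrain)]
      test <- setdiff(seq_len(P), train)
      if (length(test) < 3L) return(NA_real_)
      xs <- Xm[train, , drop = FALSE]; ys <- Ymat[train, , drop = FALSE]
      mx <- colMeans(xs); sx <- apply(xs, 2L, stats::sd)
      my <- colMeans(ys); sy <- apply(ys, 2L, stats::sd)
      if (any(sx == 0) || any(sy == 0)) return(NA_real_)
      Xz <- sweep(sweep(xs, 2L, mx), 2L, sx, "/")
      Yz <- sweep(sweep(ys, 2L, my), 2L, sy, "/")
      core <- plsCore(Xz, Yz)
      Xt <- sweep(sweep(Xm[test, , drop = FALSE], 2L, mx), 2L, sx, "/")
      Yt <- sweep(sweep(Ymat[test, , drop = FALSE], 2L, my), 2L, sy, "/")
      suppressWarnings(stats::cor(Xt %*% core$u[, 1L], Yt %*% core$v[, 1L]))
    }, numeric(1))
  }

  withSeed(seed, {
    anchors <- sample.int(P, nRep, replace = TRUE)
    oos <- oneCV(Ym, anchors)
    obs <- stats::median(oos, na.rm = TRUE)
    nullMed <- NULL; p <- NA_real_
    if (!is.null(null)) {
      nSp <- min(nNullSpin, nrow(null@permutations))
      nullMed <- vapply(seq_len(nSp), function(k) {
        stats::median(oneCV(Ym[null@permutations[k, ], , drop = FALSE],
                            anchors), na.rm = TRUE)
      }, numeric(1))
      p <- permPvalue(nullMed, obs, "greater")
    }
    list(medianR = obs, oosR = oos, pSpin = p, nullMedians = nullMed,
         nSkipped = sum(is.na(oos)))
  })
}

#' Alignment of two PLS cortical score patterns
#'
#' Pearson correlation between the component-1 x-score (e.g. gene-score)
#' parcel patterns of two models sharing the parcel index, spin-tested.
#'
#' @param modelA,modelB fitted [PLSModel-class] objects on the same parcels.
#' @param null a [SpinNull-class].
#' @param component component index (default 1).
#'
#' @return List: \code{r}, \code{pSpin}, \code{nullR}.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' X <- matrix(rnorm(200), 20); Y <- matrix(rnorm(80), 20)
#' m <- fitPLS(X, Y)
#' patternAlignment(m, m, generateSpins(atlas, 49, seed = 1))$r  # 1
#' @export
patternAlignment <- function(modelA, modelB, null, component = 1) {
  stopifnot(is(modelA, "PLSModel"), is(modelB, "PLSModel"))
  if (nrow(modelA@xScores) != nrow(modelB@xScores)) {
    stop("models must share the parcel index", call. = FALSE)
  }
  if (component > ncol(modelA@xScores) || component > ncol(modelB@xScores)) {
    stop("component index exceeds a model's component count", call. = FALSE)
  }
  spatialCorrTest(modelA@xScores[, component], modelB@xScores[, component],
                  null)
}
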