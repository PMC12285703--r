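# Spatial-autocorrelation-preserving permutations of parcellated maps:
# rotate centroids on the sphere (mirrored across hemispheres) and reassign
# rotated to original parcels by minimum-total-distance Hungarian assignment.

# Uniform random rotation: QR of a Gaussian matrix with sign fix, then
# determinant forced to +1.
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Generate spin permutations for a parcel atlas
#'
#' For each permutation a uniform random 3-D rotation is applied to the
#' left-hemisphere centroids and its mirrored counterpart to the
#' right-hemisphere centroids; since [makeAtlas()] stores the right
#' hemisphere mirrored into register, this amounts to one common rotation
#' of the reference-sphere coordinates (keeping homotopic structure).
#' Within each hemisphere the rotated centroids are matched back to the
#' original centroids by minimising the total Euclidean (chord) distance
#' with the Hungarian assignment algorithm.
#'
#' @param atlas a [ParcelAtlas-class] (unit-norm centroids, >= 2 parcels per
#'   hemisphere).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param rotations optional 3 x 3 x nPerm array of left-hemisphere rotation
#'   matrices to use instead of random ones (for reproducibility checks).
#'
#' @return A [SpinNull-class].
#' @examples
#' spins <- generateSpins(makeAtlas(20, 1), nPerm = 10, seed = 2)
#' spins
#' @export
generateSpins <- function(atlas, nPerm = 1000, seed = 1, rotations = NULL) {
  stopifnot(is(atlas, "ParcelAtlas"))
  stopifnotScalarCount(nPerm, "nPerm", min = 1L)
  hemi <- hemispheres(atlas)
  idxL <- which(hemi == "L"); idxR <- which(hemi == "R")
  if (length(idxL) < 2L || length(idxR) < 2L) {
    stop("each hemisphere needs >= 2 parcels", call. = FALSE)
  }
  cen <- centroids(atlas)
  perms <- matrix(NA_integer_, nPerm, nParcels(atlas))
  rots <- array(NA_real_, c(3L, 3L, nPerm))
  withSeed(seed, {
    for (k in seq_len(nPerm)) {
      Q <- if (is.null(rotations)) randomRotation() else rotations[, , k]
      rots[, , k] <- Q
      for (side in 1:2) {
        idx <- if (side == 1L) idxL else idxR
        orig <- cen[idx, , drop = FALSE]
        rot <- orig %*% t(Q)
        cost <- outer(rowSums(orig^2), rowSums(rot^2), "+") -
          2 * tcrossprod(orig, rot)
        cost[cost < 0] <- 0
        a <- clue::solve_LSAP(sqrt(cost))
        perms[k, idx] <- idx[as.integer(a)]
      }
    }
  })
  new("SpinNull", permutations = perms, rotations = rots,
      seed = as.integer(seed))
}

#' Spatially corrected map-to-map correlation (spin test)
#'
#' Pearson correlation between two parcel-indexed maps, with a two-tailed
#' p-value from a spin null: the first map is permuted by each spin and
#' re-correlated with the second, and
#' \eqn{p = (1 + \#\{|r_{null}| \ge |r|\}) / (1 + n_{perm})}.
#'
#' @param mapA,mapB numeric vectors indexed like the atlas the spins were
#'   generated from.
#' @param null a [SpinNull-class].
#' @param spin which map to permute, \code{"a"} (default) or \code{"b"}.
#'
#' @return List: \code{r}, \code{pSpin}, \code{nullR}.
#' @examples
#' atlas <- makeAtlas(20, 1)
#' spins <- generateSpins(atlas, nPerm = 99, seed = 2)
#' x <- rnorm(20)
#' spatialCorrTest(x, x, spins)$pSpin  # 1 / 100
#' @export
spatialCorrTest <- function(mapA, mapB, null, spin = c("a", "b")) {
  spin <- match.arg(spin)
  stopifnot(is(null, "SpinNull"))
  P <- ncol(null@permutations)
  if (length(mapA) != P || length(mapB) != P) {
    stop("maps must be indexed like the spin atlas", call. = FALSE)
  }
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0) {
    stop("constant map: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(mapA, mapB)
  spun <- if (spin == "a") mapA else mapB
  fixed <- if (spin == "a") mapB else mapA
  spunMat <- matrix(spun[t(null@permutations)], P)   # parcels x nPerm
  nullR <- as.vector(stats::cor(spunMat, fixed))
  list(r = r, pSpin = permPvalue(nullR, r, "two.sided"), nullR = nullR)
}
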