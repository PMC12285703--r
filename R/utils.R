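# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that every generator is a pure
#' function of its arguments (including the seed) and does not perturb the
#' caller's random stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @noRd
withSeed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; keeps results < 2^31.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 12289L) %% 2147483587)
}

# Column-wise Pearson correlation between two matrices of equal shape:
# returns cor(x[, j], y[, j]) for every column j.
colPearson <- function(x, y) {
  n <- nrow(x)
  cx <- sweep(x, 2L, colMeans(x))
  cy <- sweep(y, 2L, colMeans(y))
  num <- colSums(cx * cy)
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# argmax with ties treated as "no unique winner": returns NA on ties.
strictWhichMax <- function(x) {
  m <- max(x)
  idx <- which(x == m)
  if (length(idx) != 1L) NA_integer_ else idx
}

stopifnotScalarCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Permutation p-value with the +1 small-sample correction (always > 0).
permPvalue <- function(nullStats, observed, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  nullStats <- nullStats[is.finite(nullStats)]
  n <- length(nullStats)
  if (tail == "greater") {
    (1 + sum(nullStats >= observed)) / (1 + n)
  } else {
    (1 + sum(abs(nullStats) >= abs(observed))) / (1 + n)
  }
}
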