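# Plain-text interchange formats: CSV atlas/cohort tables, per-session CSV
# profile matrices with a JSON sidecar, TSV expression with a DS sidecar,
# GMT gene sets, long-format TSV developmental expression, integer CSV spins.

#' @name neuroprint-io
#' @title Read and write neuroprint data objects
#' @description
#' Plain-text readers and writers: atlas and cohort tables as CSV, spectral
#' profiles as one CSV matrix per session (subjects x parcel-by-bin
#' features, parcel index varying fastest) plus a JSON sidecar with the
#' frequency grid and provenance, gene expression as TSV with a per-gene
#' differential-stability sidecar TSV, gene sets as GMT, developmental
#' expression as long-format TSV, spin tables as integer CSV.
#' @param x object to write.
#' @param path file (or, for profiles, directory) to read from / write to.
#' @return Readers return the corresponding object; writers return
#'   \code{path} invisibly.
NULL

#' @rdname neuroprint-io
#' @export
writeAtlas <- function(x, path) {
  stopifnot(is(x, "ParcelAtlas"))
  cen <- centroids(x)
  df <- data.frame(parcel_id = parcelIds(x), hemisphere = hemispheres(x),
                   x = cen[, 1], y = cen[, 2], z = cen[, 3],
                   region_group = regionGroups(x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readAtlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cen <- as.matrix(df[, c("x", "y", "z")])
  cen <- cen / sqrt(rowSums(cen^2))   # guard against text round-off
  new("ParcelAtlas", parcelId = as.integer(df$parcel_id),
      centroid = unname(cen), hemisphere = df$hemisphere,
      regionGroup = as.character(df$region_group))
}

#' @rdname neuroprint-io
#' @export
writeCohort <- function(x, path) {
  stopifnot(is(x, "CohortDesign"))
  df <- data.frame(subject_id = subjectIds(x), pair_id = pairIds(x),
                   zygosity = zygosity(x))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  pid <- df$pair_id
  pid[!nzchar(pid)] <- NA_character_
  new("CohortDesign", subjectId = df$subject_id, pairId = pid,
      zygosity = df$zygosity)
}

#' @rdname neuroprint-io
#' @export
writeProfiles <- function(x, path) {
  stopifnot(is(x, "SpectralProfileSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x@values)
  for (t in seq_len(d[2])) {
    m <- matrix(x@values[, t, , , drop = FALSE], d[1], d[3] * d[4])
    utils::write.csv(
      data.frame(subject_id = x@subjectIds, m, check.names = FALSE),
      file.path(path, paste0(x@sessionIds[t], ".csv")), row.names = FALSE)
  }
  sidecar <- list(freq = x@freq, subject_ids = x@subjectIds,
                  session_ids = x@sessionIds, n_parcels = d[3],
                  meta = x@meta)
  jsonlite::write_json(sidecar, file.path(path, "profiles.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readProfiles <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "profiles.json"),
                                 simplifyVector = TRUE)
  nSes <- length(sidecar$session_ids)
  nSub <- length(sidecar$subject_ids)
  P <- sidecar$n_parcels
  nF <- length(sidecar$freq)
  vals <- array(NA_real_, c(nSub, nSes, P, nF))
  for (t in seq_len(nSes)) {
    df <- utils::read.csv(file.path(path, paste0(sidecar$session_ids[t], ".csv")),
                          check.names = FALSE)
    vals[, t, , ] <- array(as.matrix(df[, -1L, drop = FALSE]), c(nSub, P, nF))
  }
  meta <- sidecar$meta
  if (is.null(meta)) meta <- list()
  new("SpectralProfileSet", values = vals, freq = as.numeric(sidecar$freq),
      subjectIds = sidecar$subject_ids, sessionIds = sidecar$session_ids,
      meta = meta)
}

#' @rdname neuroprint-io
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "GeneExpressionMatrix"))
  m <- exprValues(x)
  utils::write.table(
    data.frame(parcel = seq_len(nrow(m)), m, check.names = FALSE),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  dsPath <- paste0(path, ".ds.tsv")
  utils::write.table(
    data.frame(gene = x@geneIds, ds = x@ds), dsPath,
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ds <- utils::read.delim(paste0(path, ".ds.tsv"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  new("GeneExpressionMatrix", values = unname(m), geneIds = colnames(m),
      ds = as.numeric(ds$ds[match(colnames(m), ds$gene)]), meta = list())
}

#' @rdname neuroprint-io
#' @export
writeGmt <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, "na", x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname neuroprint-io
#' @export
writeDevExpression <- function(x, path) {
  stopifnot(is(x, "DevExpressionSet"))
  d <- dim(x@values)
  df <- data.frame(
    region = rep(x@regions, times = d[2] * d[3]),
    stage_index = rep(rep(x@stages, each = d[1]), times = d[3]),
    gene = rep(x@geneIds, each = d[1] * d[2]),
    value = as.vector(x@values)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readDevExpression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  regions <- unique(df$region)
  stages <- sort(unique(df$stage_index))
  genes <- unique(df$gene)
  vals <- array(NA_real_, c(length(regions), length(stages), length(genes)))
  idx <- cbind(match(df$region, regions), match(df$stage_index, stages),
               match(df$gene, genes))
  vals[idx] <- df$value
  new("DevExpressionSet", values = vals, regions = regions,
      stages = as.integer(stages), geneIds = genes, meta = list())
}

#' @rdname neuroprint-io
#' @export
writeSpins <- function(x, path) {
  stopifnot(is(x, "SpinNull"))
  utils::write.table(x@permutations, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname neuroprint-io
#' @export
readSpins <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "integer"
  nPerm <- nrow(m)
  rots <- array(rep(diag(3), nPerm), c(3L, 3L, nPerm))  # rotations not stored
  new("SpinNull", permutations = unname(m), rotations = rots, seed = NA_integer_)
}
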