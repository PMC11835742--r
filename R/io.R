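# Delimited text (tab-separated) is the canonical interchange format for
# matrices; readers validate shape and numeric content and report the
# offending line on failure.

.read_numeric_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(what, " file is empty: ", path)
  rows <- strsplit(trimws(lines), "[\t ,]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(what, " file ", path, ": ragged row at line ",
         which(ncols != ncols[1L])[1L])
  m <- matrix(NA_real_, length(rows), ncols[1L])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(what, " file ", path, ": non-finite or non-numeric value at line ",
           i, ", column ", bad[1L], " ('", rows[[i]][bad[1L]], "')")
    m[i, ] <- v
  }
  m
}

#' Read a parcellated BOLD matrix from delimited text
#'
#' @param path text file, one region per row (tab-, space- or
#'   comma-separated), volumes as columns.
#' @param tr repetition time in seconds.
#' @param transpose set TRUE when the file stores volumes as rows.
#' @return a [BoldTimeseries-class].
#' @export
readTimeseries <- function(path, tr, transpose = FALSE) {
  m <- .read_numeric_matrix(path, "timeseries")
  if (transpose) m <- t(m)
  BoldTimeseries(m, tr)
}

#' Read parcel geometry from a 3-column coordinate file
#'
#' @param path text file of centroid coordinates in mm, one region per
#'   row, 3 columns.
#' @param labelsPath optional text file with one RSN label per line.
#' @return a [ParcelGeometry-class].
#' @export
readGeometry <- function(path, labelsPath = NULL) {
  m <- .read_numeric_matrix(path, "coordinates")
  if (ncol(m) != 3L)
    stop("coordinates file ", path, " must have 3 columns, found ", ncol(m))
  labels <- NULL
  if (!is.null(labelsPath)) {
    labels <- trimws(readLines(labelsPath))
    labels <- labels[nzchar(labels)]
    if (length(labels) != nrow(m))
      stop("labels file ", labelsPath, " has ", length(labels),
           " entries for ", nrow(m), " regions")
  }
  ParcelGeometry(m, labels)
}

#' Read a square connectome matrix from delimited text
#'
#' @param path text file holding an N x N nonnegative symmetric matrix.
#' @return numeric matrix.
#' @export
readConnectome <- function(path) {
  m <- .read_numeric_matrix(path, "connectome")
  if (nrow(m) != ncol(m))
    stop("connectome file ", path, " is not square: ", nrow(m), " x ", ncol(m))
  m
}

#' Write a numeric matrix as tab-separated text
#'
#' @param m numeric matrix.
#' @param path output file.
#' @export
writeMatrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a TurbulenceProfile to JSON plus a node-metastability table
#'
#' Scalars and per-scale maps go to \code{<stem>.json}; the regions x
#' scales node-metastability matrix goes to \code{<stem>_node_metastability.tsv}.
#'
#' @param profile a [TurbulenceProfile-class].
#' @param stem output path without extension.
#' @return paths written, invisibly.
#' @export
writeProfile <- function(profile, stem) {
  js <- list(
    turbulence = as.list(turbulence(profile)),
    cascade_flow = as.list(cascadeFlow(profile)),
    information_cascade = informationCascade(profile),
    information_transfer = as.list(informationTransfer(profile)),
    transfer_sign_convention = "negative slope of log mean correlation vs log distance; larger = faster spatial decay",
    lambdas = profile@lambdas, tr = profile@tr)
  jpath <- paste0(stem, ".json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, digits = NA)
  mpath <- paste0(stem, "_node_metastability.tsv")
  writeMatrix(nodeMetastability(profile), mpath)
  invisible(c(jpath, mpath))
}

#' Write a synthetic cohort to disk
#'
#' One tab-separated BOLD matrix per subject plus a JSON manifest listing
#' subject ids, groups, clinical scores, the master seed and an echo of
#' the cohort specification.
#'
#' @param cohort list of [SubjectRecord-class] from [generateCohort()].
#' @param spec the [CohortSpec-class] used.
#' @param dir output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
writeCohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(cohort, function(s) {
    f <- file.path(dir, paste0(s@subjectId, "_bold.tsv"))
    writeMatrix(s@bold@data, f)
    list(subject_id = s@subjectId, group = s@group,
      hamd6_baseline = s@hamd6Baseline, hamd6_pct_change = s@hamd6PctChange,
      bold_file = basename(f))
  })
  manifest <- list(
    spec = list(n_regions = spec@nRegions, n_volumes = spec@nVolumes,
      tr = spec@tr, group_sizes = spec@groupSizes, group_G = spec@groupG,
      outcome_correlation = spec@outcomeCorrelation, seed = spec@seed),
    subjects = subjects)
  mpath <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(mpath)
}
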