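## Recording bundle I/O.
##
## A recording is stored as a directory ("recording bundle") mirroring the
## instrument-style hierarchical layout:
##
##   <path>/
##     meta.json       subject_id, maneuver, acquired_at, dimensions, format
##     mz_axis.txt     one m/z grid value per line (full precision, %.17g)
##     times.txt       one acquisition time (s) per line
##     capnostat.txt   one capnostat reading per line      (aux channel)
##     spectra.f64     little-endian float64 intensity payload, spectra in
##                     acquisition order, m/z-major within each spectrum
##
## The layout is lossless for every declared field and is documented here and
## in the package vignette. Unknown extra files are ignored with a warning.

.BUNDLE_FILES <- c("meta.json", "mz_axis.txt", "times.txt",
                   "capnostat.txt", "spectra.f64")

.writeNumLines <- function(x, path) writeLines(sprintf("%.17g", x), path)
.readNumLines <- function(path) as.numeric(readLines(path))

#' Write a recording bundle
#'
#' Serializes a [RawRecording-class] to the documented on-disk bundle layout
#' (see [readRecording()]); the round trip is exact at full floating-point
#' precision.
#'
#' @param rec A valid [RawRecording-class].
#' @param path Directory to create.
#' @param overwrite Overwrite an existing bundle at `path`? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, overwrite = FALSE) {
  stopifnot(is(rec, "RawRecording"))
  validObject(rec)
  if (file.exists(path) && !overwrite)
    stop("path already exists (use overwrite = TRUE): ", path)
  if (file.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  meta <- c(rec@metadata,
            list(format = "breathVOC-recording-bundle/1",
                 n_spectra = nrow(rec@spectra),
                 n_mz = length(rec@mzAxis)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeNumLines(rec@mzAxis, file.path(path, "mz_axis.txt"))
  .writeNumLines(rec@times, file.path(path, "times.txt"))
  .writeNumLines(rec@capnostat, file.path(path, "capnostat.txt"))
  con <- file(file.path(path, "spectra.f64"), "wb")
  on.exit(close(con))
  ## row-major (time-major) order: one spectrum after another
  writeBin(as.vector(t(rec@spectra)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a recording bundle
#'
#' Reads a directory written by [writeRecording()] back into a
#' [RawRecording-class]. Mandatory members are `meta.json`, `mz_axis.txt`,
#' `times.txt`, `capnostat.txt` and `spectra.f64`; a missing member raises a
#' format error naming it, and unknown extra files are ignored with a
#' warning.
#'
#' @param path Bundle directory.
#' @return A validated [RawRecording-class].
#' @export
readRecording <- function(path) {
  if (!dir.exists(path)) stop("no recording bundle at ", path)
  present <- list.files(path)
  for (f in .BUNDLE_FILES)
    if (!f %in% present)
      stop("format error: mandatory dataset '", sub("\\..*$", "", f),
           "' missing from bundle ", path)
  extra <- setdiff(present, .BUNDLE_FILES)
  if (length(extra))
    warning("ignoring unknown bundle member(s): ",
            paste(extra, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  mz <- .readNumLines(file.path(path, "mz_axis.txt"))
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("validation error: mz_axis is not strictly increasing")
  times <- .readNumLines(file.path(path, "times.txt"))
  cap <- .readNumLines(file.path(path, "capnostat.txt"))
  nT <- as.integer(meta$n_spectra %||% length(times))
  nM <- as.integer(meta$n_mz %||% length(mz))
  con <- file(file.path(path, "spectra.f64"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = nT * nM, size = 8,
                  endian = "little")
  if (length(vals) != nT * nM)
    stop("format error: spectra payload has ", length(vals),
         " values, expected ", nT * nM)
  spectra <- matrix(vals, nrow = nT, ncol = nM, byrow = TRUE)
  meta <- meta[setdiff(names(meta), c("format", "n_spectra", "n_mz"))]
  RawRecording(mzAxis = mz, spectra = spectra, times = times,
               capnostat = cap, metadata = as.list(meta))
}

#' Write a feature matrix to CSV (with a JSON sidecar)
#'
#' Samples in rows, consensus m/z (3 decimals) in columns; prevalence,
#' normalization state and sample metadata go to `<path>.json`.
#'
#' @param fm A [BreathFeatureSet-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  m <- intensityMatrix(fm)
  colnames(m) <- sprintf("%.3f", featureMz(fm))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  side <- list(
    feature_mz = featureMz(fm),
    prevalence = prevalence(fm),
    normalized = isNormalized(fm),
    internal_standard_mz = S4Vectors::metadata(fm)$internalStandardMz,
    sample_meta = as.data.frame(SummarizedExperiment::colData(fm)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
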