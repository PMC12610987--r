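#' @import methods
#' @importFrom stats median rnorm runif rbinom setNames predict
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' RawRecording: one time-resolved PTR-TOF-MS sampling session
#'
#' Per-second full mass spectra on a shared dense m/z grid, together with the
#' capnostat (CO2 sensor) auxiliary channel and session metadata. Spectra are
#' stored as a time-by-m/z matrix of intensities in counts per second (cps).
#'
#' @slot mzAxis Strictly increasing numeric m/z grid (Da), shared by all
#'   spectra.
#' @slot spectra Numeric matrix, one row per acquired spectrum (time-ordered),
#'   one column per grid point; intensities in cps, non-negative.
#' @slot times Acquisition times in seconds from the start of the session.
#' @slot capnostat One capnostat reading (arbitrary units) per spectrum.
#' @slot metadata List with at least `subject_id`, `maneuver`
#'   (`"tidal"` or `"forced"`) and `acquired_at`.
#'
#' @seealso [readRecording()], [writeRecording()], [simulateRecording()]
#' @export
setClass("RawRecording",
  representation(
    mzAxis = "numeric",
    spectra = "matrix",
    times = "numeric",
    capnostat = "numeric",
    metadata = "list"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character(0)
  nT <- nrow(object@spectra)
  if (nT == 0L) msg <- c(msg, "recording has no spectra")
  if (length(object@times) != nT)
    msg <- c(msg, "length(times) must equal nrow(spectra)")
  if (length(object@capnostat) != nT)
    msg <- c(msg, "length(capnostat) must equal nrow(spectra)")
  if (ncol(object@spectra) != length(object@mzAxis))
    msg <- c(msg, "ncol(spectra) must equal length(mzAxis)")
  if (length(object@mzAxis) > 1L && any(diff(object@mzAxis) <= 0))
    msg <- c(msg, "mzAxis must be strictly increasing")
  if (nT > 0L && any(object@spectra < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param mzAxis,spectra,times,capnostat,metadata See the slot documentation
#'   in [RawRecording-class].
#' @return A validated [RawRecording-class] object.
#' @export
RawRecording <- function(mzAxis, spectra, times, capnostat,
                         metadata = list()) {
  new("RawRecording", mzAxis = as.numeric(mzAxis),
      spectra = spectra, times = as.numeric(times),
      capnostat = as.numeric(capnostat), metadata = metadata)
}

#' SampleSpectrum: composite exhalation-phase spectrum for one sample
#'
#' @slot mzAxis m/z grid (Da), same length as the source recording's axis.
#' @slot intensity Composite intensity (cps), mean of the selected spectra
#'   after Savitzky-Golay smoothing along m/z.
#' @slot nSpectraUsed Number of source spectra combined (>= 1).
#' @slot provenance Integer time indices of the selected spectra.
#' @export
setClass("SampleSpectrum",
  representation(
    mzAxis = "numeric",
    intensity = "numeric",
    nSpectraUsed = "integer",
    provenance = "integer"
  )
)

setValidity("SampleSpectrum", function(object) {
  msg <- character(0)
  if (length(object@intensity) != length(object@mzAxis))
    msg <- c(msg, "intensity and mzAxis lengths differ")
  if (object@nSpectraUsed < 1L) msg <- c(msg, "nSpectraUsed must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CalibrationModel: quadratic mass-axis correction in sqrt(m/z) space
#'
#' @slot referenceMzs The reference masses the model was fitted to (Da).
#' @slot coefficients Coefficients `(c0, c1, c2)` of
#'   `sqrt(mz_corrected) = c0 + c1 * sqrt(mz) + c2 * mz`.
#' @slot residualPpm Signed residual (ppm) at each reference after
#'   correction, measured on re-detected centroids.
#' @export
setClass("CalibrationModel",
  representation(
    referenceMzs = "numeric",
    coefficients = "numeric",
    residualPpm = "numeric"
  )
)

#' BreathPhaseResult: exhalation-phase spectrum selection for one recording
#'
#' @slot selected Integer time indices of retained (end-tidal) spectra.
#' @slot cycleCount Number of complete respiratory cycles detected.
#' @slot flags Data frame with per-spectrum logicals `water_ok` (water adduct
#'   above threshold) and `tracer_coincidence` (>= 2 of 3 tracer VOCs with a
#'   local maximum within the coincidence window).
#' @export
setClass("BreathPhaseResult",
  representation(
    selected = "integer",
    cycleCount = "integer",
    flags = "data.frame"
  )
)

setValidity("BreathPhaseResult", function(object) {
  msg <- character(0)
  if (object@cycleCount < 0L) msg <- c(msg, "cycleCount must be >= 0")
  n <- nrow(object@flags)
  if (length(object@selected) &&
      (min(object@selected) < 1L || max(object@selected) > n))
    msg <- c(msg, "selected indices outside the recording")
  if (length(msg)) msg else TRUE
})

#' QCReport: per-recording quality-control verdict
#'
#' Pass/fail flags for the three acquisition QC criteria (capnostat maximum
#' below the exclusion threshold, worst calibrant residual below the ppm
#' limit, at least the minimum number of complete respiratory cycles) and
#' their conjunction.
#'
#' @slot capnostatPass,calibrantPass,cyclesPass,overallPass Logical flags;
#'   `overallPass` is the conjunction of the three criteria.
#' @slot details Named list with the measured values and thresholds.
#' @export
setClass("QCReport",
  representation(
    capnostatPass = "logical",
    calibrantPass = "logical",
    cyclesPass = "logical",
    overallPass = "logical",
    details = "list"
  )
)

setValidity("QCReport", function(object) {
  ok <- identical(object@overallPass,
                  object@capnostatPass && object@calibrantPass &&
                    object@cyclesPass)
  if (!ok) "overallPass must be the conjunction of the three criteria" else TRUE
})

#' BreathFeatureSet: aligned cohort feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per consensus
#' m/z feature and one column per breath sample. `rowData` carries the
#' consensus centroid (`mz`) and the fraction of samples in which the feature
#' was detected (`prevalence`); `colData` carries sample metadata (subject,
#' maneuver, diagnosis group, BDR label where present). The single assay
#' `"intensity"` holds integrated peak intensities, dimensionless after
#' internal-standard normalization (`metadata()$normalized`).
#'
#' @seealso [alignFeatures()], [normalizeFeatures()], [filterModelFeatures()]
#' @export
setClass("BreathFeatureSet", contains = "SummarizedExperiment")

#' Construct a BreathFeatureSet
#'
#' @param values Numeric matrix, samples in rows and features in columns
#'   (transposed internally to the features-by-samples Bioconductor layout).
#' @param featureMz Numeric vector of consensus feature m/z values (Da).
#' @param prevalence Numeric vector in `[0, 1]`, fraction of samples in which
#'   each feature was detected before zero-imputation.
#' @param sampleData Data frame of per-sample metadata (one row per sample).
#' @param normalized Logical; `TRUE` once intensities have been divided by
#'   the internal-standard feature.
#' @param internalStandardMz The internal standard m/z once normalized.
#' @return A [BreathFeatureSet-class].
#' @export
BreathFeatureSet <- function(values, featureMz,
                             prevalence = rep(NA_real_, length(featureMz)),
                             sampleData = NULL, normalized = FALSE,
                             internalStandardMz = NA_real_) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(featureMz))
  m <- t(values)
  rownames(m) <- sprintf("mz_%.4f", featureMz)
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(mz = featureMz, prevalence = prevalence,
                                   row.names = rownames(m)),
    colData = S4Vectors::DataFrame(sampleData)
  )
  out <- new("BreathFeatureSet", se)
  S4Vectors::metadata(out)$normalized <- normalized
  S4Vectors::metadata(out)$internalStandardMz <- internalStandardMz
  out
}

setValidity("BreathFeatureSet", function(object) {
  msg <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "prevalence") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'prevalence'")
  else {
    p <- rd$prevalence
    if (any(!is.na(p) & (p < 0 | p > 1)))
      msg <- c(msg, "prevalence must lie in [0, 1]")
  }
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: resampling-consensus feature selection outcome
#'
#' @slot medianImportance Named list (one element per maneuver) of per-feature
#'   median importance vectors.
#' @slot rankedLists Named list of per-maneuver ranked feature name vectors,
#'   truncated at `topK`.
#' @slot topK Truncation depth of the per-maneuver ranked lists.
#' @slot consensusFeatures Intersection of the per-maneuver top-`topK` lists.
#' @slot nIterations Resampling iterations per maneuver.
#' @slot subsampleFraction Fraction of the training set drawn per iteration.
#' @slot seeds Integer seeds used per maneuver.
#' @export
setClass("SelectionResult",
  representation(
    medianImportance = "list",
    rankedLists = "list",
    topK = "integer",
    consensusFeatures = "character",
    nIterations = "integer",
    subsampleFraction = "numeric",
    seeds = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  for (lst in object@rankedLists)
    if (length(lst) > object@topK)
      msg <- c(msg, "ranked lists must be truncated at topK")
  for (lst in object@rankedLists)
    if (!all(object@consensusFeatures %in% lst))
      msg <- c(msg, "consensus features must appear in every ranked list")
  if (length(msg)) msg else TRUE
})

#' ModelReport: threshold metrics for a fitted classifier
#'
#' @slot endpoint `"diagnosis"` or `"bdr"`.
#' @slot auc Area under the ROC curve from predicted probabilities.
#' @slot sensitivity,specificity,ppv,npv Confusion metrics at `threshold`
#'   (probability >= threshold is called positive). `NA` when a denominator
#'   is empty.
#' @slot threshold Probability threshold (default 0.5).
#' @slot cvScheme `"holdout"`, `"stratified-kfold"` or `"loo"`.
#' @slot nTrain,nTest Sample counts.
#' @export
setClass("ModelReport",
  representation(
    endpoint = "character",
    auc = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    ppv = "numeric",
    npv = "numeric",
    threshold = "numeric",
    cvScheme = "character",
    nTrain = "integer",
    nTest = "integer"
  )
)

setValidity("ModelReport", function(object) {
  vals <- c(object@auc, object@sensitivity, object@specificity,
            object@ppv, object@npv)
  if (any(!is.na(vals) & (vals < 0 | vals > 1)))
    "all metrics must lie in [0, 1]" else TRUE
})
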