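#' @name accessors
#' @title Accessors for breathVOC classes
#'
#' @description Slot accessors: `mzAxis()`, `spectra()`, `acqTimes()`,
#' `capnostat()` for [RawRecording-class]; `featureMz()`, `prevalence()`,
#' `intensityMatrix()`, `isNormalized()` for [BreathFeatureSet-class];
#' `cycleCount()`, `selectedSpectra()` for [BreathPhaseResult-class];
#' `residualPpm()` for [CalibrationModel-class]; `overallPass()` for
#' [QCReport-class]; `consensusFeatures()` for [SelectionResult-class].
#'
#' @param object An object of the documented class.
#' @return The slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("mzAxis", function(object) standardGeneric("mzAxis"))
#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))
#' @rdname accessors
#' @export
setGeneric("acqTimes", function(object) standardGeneric("acqTimes"))
#' @rdname accessors
#' @export
setGeneric("capnostat", function(object) standardGeneric("capnostat"))
#' @rdname accessors
#' @export
setGeneric("featureMz", function(object) standardGeneric("featureMz"))
#' @rdname accessors
#' @export
setGeneric("prevalence", function(object) standardGeneric("prevalence"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(object)
  standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("cycleCount", function(object) standardGeneric("cycleCount"))
#' @rdname accessors
#' @export
setGeneric("selectedSpectra", function(object)
  standardGeneric("selectedSpectra"))
#' @rdname accessors
#' @export
setGeneric("residualPpm", function(object) standardGeneric("residualPpm"))
#' @rdname accessors
#' @export
setGeneric("overallPass", function(object) standardGeneric("overallPass"))
#' @rdname accessors
#' @export
setGeneric("consensusFeatures", function(object)
  standardGeneric("consensusFeatures"))

#' @rdname accessors
setMethod("mzAxis", "RawRecording", function(object) object@mzAxis)
#' @rdname accessors
setMethod("mzAxis", "SampleSpectrum", function(object) object@mzAxis)
#' @rdname accessors
setMethod("spectra", "RawRecording", function(object) object@spectra)
#' @rdname accessors
setMethod("acqTimes", "RawRecording", function(object) object@times)
#' @rdname accessors
setMethod("capnostat", "RawRecording", function(object) object@capnostat)

#' @rdname accessors
setMethod("featureMz", "BreathFeatureSet", function(object)
  SummarizedExperiment::rowData(object)$mz)
#' @rdname accessors
setMethod("prevalence", "BreathFeatureSet", function(object)
  SummarizedExperiment::rowData(object)$prevalence)
#' @rdname accessors
setMethod("intensityMatrix", "BreathFeatureSet", function(object)
  t(SummarizedExperiment::assay(object, "intensity")))
#' @rdname accessors
setMethod("isNormalized", "BreathFeatureSet", function(object)
  isTRUE(S4Vectors::metadata(object)$normalized))

#' @rdname accessors
setMethod("cycleCount", "BreathPhaseResult", function(object)
  object@cycleCount)
#' @rdname accessors
setMethod("selectedSpectra", "BreathPhaseResult", function(object)
  object@selected)
#' @rdname accessors
setMethod("residualPpm", "CalibrationModel", function(object)
  object@residualPpm)
#' @rdname accessors
setMethod("overallPass", "QCReport", function(object) object@overallPass)
#' @rdname accessors
setMethod("consensusFeatures", "SelectionResult", function(object)
  object@consensusFeatures)

setMethod("show", "RawRecording", function(object) {
  md <- object@metadata
  cat("RawRecording:", nrow(object@spectra), "spectra x",
      length(object@mzAxis), "m/z points\n")
  cat("  m/z range:", sprintf("%.3f-%.3f", min(object@mzAxis),
                              max(object@mzAxis)), "Da\n")
  cat("  duration:", sprintf("%.0f s", diff(range(object@times)) +
                               mean(diff(object@times))), "\n")
  if (!is.null(md$subject_id))
    cat("  subject:", md$subject_id, " maneuver:",
        md$maneuver %||% "?", "\n")
  invisible(object)
})

setMethod("show", "BreathPhaseResult", function(object) {
  cat("BreathPhaseResult:", object@cycleCount, "respiratory cycles,",
      length(object@selected), "of", nrow(object@flags),
      "spectra selected\n")
  invisible(object)
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: quadratic in sqrt(m/z)\n")
  cat("  references:", paste(sprintf("%.4f", object@referenceMzs),
                             collapse = ", "), "Da\n")
  cat("  residuals :", paste(sprintf("%+.2f", object@residualPpm),
                             collapse = ", "), "ppm\n")
  invisible(object)
})

setMethod("show", "QCReport", function(object) {
  mark <- function(x) if (x) "PASS" else "FAIL"
  cat("QCReport:", if (object@overallPass) "PASS" else "FAIL", "\n")
  cat("  capnostat:", mark(object@capnostatPass),
      sprintf("(max %.2f, limit %.2f)", object@details$capnostat_max,
              object@details$capnostat_limit), "\n")
  cat("  calibrant:", mark(object@calibrantPass),
      sprintf("(worst %.1f ppm, limit %.0f)",
              object@details$calibrant_worst_ppm,
              object@details$calibrant_limit_ppm), "\n")
  cat("  cycles   :", mark(object@cyclesPass),
      sprintf("(%d, minimum %d)", object@details$cycle_count,
              object@details$min_cycles), "\n")
  invisible(object)
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@consensusFeatures),
      "consensus features from", length(object@rankedLists),
      sprintf("maneuvers (top %d, %d iterations, fraction %.3f)\n",
              object@topK, object@nIterations, object@subsampleFraction))
  if (length(object@consensusFeatures))
    cat("  ", paste(head(object@consensusFeatures, 10), collapse = ", "),
        if (length(object@consensusFeatures) > 10) "..." else "", "\n")
  invisible(object)
})

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport [%s, %s]: AUC %.3f\n", object@endpoint,
              object@cvScheme, object@auc))
  cat(sprintf(
    "  at threshold %.2f: sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
    object@threshold, object@sensitivity, object@specificity,
    object@ppv, object@npv))
  cat(sprintf("  n(train) = %d, n(test) = %d\n", object@nTrain, object@nTest))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a ModelReport to a one-row data frame
#'
#' @param x A [ModelReport-class].
#' @param ... Ignored.
#' @return One-row data frame of the report fields.
#' @export
as.data.frame.ModelReport <- function(x, ...) {
  data.frame(endpoint = x@endpoint, cv_scheme = x@cvScheme, auc = x@auc,
             sensitivity = x@sensitivity, specificity = x@specificity,
             ppv = x@ppv, npv = x@npv, threshold = x@threshold,
             n_train = x@nTrain, n_test = x@nTest)
}
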