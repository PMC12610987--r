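## Preprocessing: mass recalibration, EIC extraction, breath-phase
## segmentation and the acquisition QC cascade.

#' IonTrace: extracted ion current for one target ion
#'
#' @slot targetMz Target m/z (Da).
#' @slot window Half-width of the extraction window (Da).
#' @slot intensity One integrated intensity (cps) per spectrum.
#' @slot times Acquisition times (s), parallel to `intensity`.
#' @export
setClass("IonTrace",
  representation(targetMz = "numeric", window = "numeric",
                 intensity = "numeric", times = "numeric"))

setValidity("IonTrace", function(object) {
  msg <- character(0)
  if (object@window <= 0) msg <- c(msg, "window must be positive")
  if (length(object@intensity) != length(object@times))
    msg <- c(msg, "intensity and times lengths differ")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IonTrace", function(object) {
  cat(sprintf("IonTrace m/z %.4f (+/- %.3f Da): %d points, max %.3g cps\n",
              object@targetMz, object@window, length(object@intensity),
              max(object@intensity)))
  invisible(object)
})

## Centroid of the peak nearest `targetMz` in a single spectrum: apex within
## +/- window, refined by the vertex of a parabola through the log
## intensities at apex +/- 1 (exact for a noise-free Gaussian, sub-grid
## accurate otherwise). Falls back to the intensity-weighted mean over the
## contiguous above-half-maximum region when the log fit is unavailable.
## Returns NA if no credible apex.
.detectCentroid <- function(mzAxis, intensity, targetMz, window = 0.2,
                            minIntensity = 100) {
  idx <- which(abs(mzAxis - targetMz) <= window)
  if (!length(idx)) return(NA_real_)
  y <- intensity[idx]
  apex <- which.max(y)
  if (y[apex] < minIntensity) return(NA_real_)
  if (apex > 1L && apex < length(y) && all(y[(apex - 1L):(apex + 1L)] > 0)) {
    x3 <- mzAxis[idx][(apex - 1L):(apex + 1L)]
    l3 <- log(y[(apex - 1L):(apex + 1L)])
    co <- try(solve(cbind(1, x3, x3^2), l3), silent = TRUE)
    if (!inherits(co, "try-error") && is.finite(co[3]) && co[3] < 0) {
      vertex <- -co[2] / (2 * co[3])
      if (vertex >= x3[1] && vertex <= x3[3]) return(vertex)
    }
  }
  half <- y[apex] / 2
  lo <- apex; while (lo > 1L && y[lo - 1L] >= half) lo <- lo - 1L
  hi <- apex; while (hi < length(y) && y[hi + 1L] >= half) hi <- hi + 1L
  sel <- lo:hi
  sum(mzAxis[idx][sel] * y[sel]) / sum(y[sel])
}

#' Recalibrate the mass axis against reference ions
#'
#' Detects the centroid of each reference peak in the time-averaged spectrum
#' and fits an exact quadratic correction in sqrt(m/z) space (the TOF
#' flight-time convention), `sqrt(mz') = c0 + c1*sqrt(mz) + c2*mz`, through
#' the three (observed centroid, reference) pairs. Residuals are then
#' measured on centroids re-detected on the corrected axis.
#'
#' @param rec A [RawRecording-class].
#' @param referenceMzs Reference masses (Da); default the three PerMaSCal
#'   ions m/z 21.0220, 203.94299, 330.85.
#' @param searchWindow Half-width (Da) of the centroid search window.
#' @param minIntensity Minimum apex intensity (cps, on the mean spectrum)
#'   for a reference peak to count as detected.
#' @return List with `recording` (corrected axis) and `model`
#'   ([CalibrationModel-class] with signed per-reference residuals in ppm).
#' @export
recalibrate <- function(rec, referenceMzs = c(21.0220, 203.94299, 330.85),
                        searchWindow = 0.2, minIntensity = 100) {
  stopifnot(is(rec, "RawRecording"))
  if (length(referenceMzs) != 3L)
    stop("exactly three reference masses are required")
  meanSpec <- colMeans(rec@spectra)
  cent <- vapply(referenceMzs, function(m)
    .detectCentroid(rec@mzAxis, meanSpec, m, searchWindow, minIntensity),
    numeric(1))
  if (anyNA(cent))
    stop("calibration error: reference peak at m/z ",
         paste(sprintf("%.4f", referenceMzs[is.na(cent)]), collapse = ", "),
         " not found")
  s <- sqrt(cent)
  A <- cbind(1, s, s^2)
  coef <- solve(A, sqrt(referenceMzs))
  sAll <- sqrt(rec@mzAxis)
  corrected <- (coef[1] + coef[2] * sAll + coef[3] * sAll^2)^2
  if (any(diff(corrected) <= 0))
    stop("calibration error: corrected axis is not monotone over the range")
  recOut <- RawRecording(mzAxis = corrected, spectra = rec@spectra,
                         times = rec@times, capnostat = rec@capnostat,
                         metadata = rec@metadata)
  centNew <- vapply(referenceMzs, function(m)
    .detectCentroid(corrected, meanSpec, m, searchWindow, minIntensity),
    numeric(1))
  resid <- .ppmError(referenceMzs, centNew)
  new("CalibrationModel", referenceMzs = referenceMzs,
      coefficients = as.numeric(coef),
      residualPpm = setNames(resid, sprintf("%.4f", referenceMzs))) -> model
  list(recording = recOut, model = model)
}

#' Extract an ion current trace
#'
#' Per-spectrum sum of intensities over `[targetMz - window,
#' targetMz + window]`.
#'
#' @param rec A [RawRecording-class].
#' @param targetMz Target ion m/z (Da).
#' @param window Half-width in Da (default 0.05).
#' @return An [IonTrace-class].
#' @export
extractEIC <- function(rec, targetMz, window = 0.05) {
  stopifnot(is(rec, "RawRecording"))
  if (targetMz - window < min(rec@mzAxis) ||
      targetMz + window > max(rec@mzAxis))
    stop("range error: EIC window [", targetMz - window, ", ",
         targetMz + window, "] outside the m/z axis")
  idx <- which(abs(rec@mzAxis - targetMz) <= window)
  inten <- if (length(idx) == 1L) rec@spectra[, idx]
           else rowSums(rec@spectra[, idx, drop = FALSE])
  new("IonTrace", targetMz = targetMz, window = window,
      intensity = as.numeric(inten), times = rec@times)
}

#' Delineate breath phases from the water adduct and tracer VOCs
#'
#' A spectrum is retained as end-tidal iff (a) the water-adduct trace exceeds
#' `waterThreshold` at that time and (b) at least two of the three tracer-VOC
#' traces show a local maximum within `coincidence` spectra. Local maxima are
#' strict maxima over a +/- 2-spectrum neighbourhood of the Savitzky-Golay
#' smoothed trace (the first index of a plateau counts). The cycle count is
#' the number of maximal runs of water-above-threshold spectra.
#'
#' @param waterTrace [IonTrace-class] for the water adduct.
#' @param tracerTraces List of three tracer [IonTrace-class] objects on the
#'   same time base.
#' @param waterThreshold Water-adduct retention threshold in cps
#'   (default 2e5).
#' @param coincidence Tracer-maximum coincidence window in spectra
#'   (default 1).
#' @param minTracers Minimum number of coincident tracer maxima (default 2).
#' @param smoothWindow,smoothOrder Savitzky-Golay smoothing of the tracer
#'   traces before maximum detection (defaults 5, 2).
#' @return A [BreathPhaseResult-class].
#' @export
segmentBreaths <- function(waterTrace, tracerTraces, waterThreshold = 2e5,
                           coincidence = 1L, minTracers = 2L,
                           smoothWindow = 5L, smoothOrder = 2L) {
  stopifnot(is(waterTrace, "IonTrace"))
  n <- length(waterTrace@intensity)
  for (tr in tracerTraces) {
    stopifnot(is(tr, "IonTrace"))
    if (length(tr@intensity) != n)
      stop("contract error: traces do not share the time base")
  }
  waterOk <- waterTrace@intensity > waterThreshold

  maxMat <- vapply(tracerTraces, function(tr)
    .localMaxima(.sgSmooth(tr@intensity, smoothWindow, smoothOrder), k = 2L),
    logical(n))
  if (is.null(dim(maxMat))) maxMat <- matrix(maxMat, nrow = n)
  ## a tracer counts at time i if it peaks anywhere in i +/- coincidence
  near <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - coincidence):min(n, i + coincidence)
    colSums(maxMat[w, , drop = FALSE]) > 0
  }, logical(length(tracerTraces)))
  nearCount <- if (is.null(dim(near))) near else colSums(near)
  tracerOk <- nearCount >= minTracers

  selected <- which(waterOk & tracerOk)
  runs <- rle(waterOk)
  cycles <- sum(runs$values)
  new("BreathPhaseResult", selected = as.integer(selected),
      cycleCount = as.integer(cycles),
      flags = data.frame(water_ok = waterOk, tracer_coincidence = tracerOk))
}

#' Quality-control verdict for one recording
#'
#' Applies the acquisition QC cascade: capnostat maximum at or below the
#' exclusion threshold (3.5 units), worst absolute calibrant residual below
#' the ppm limit (100 ppm), and at least the minimum number of complete
#' respiratory cycles (3). A recording passes overall iff it passes all
#' three.
#'
#' @param rec A [RawRecording-class].
#' @param phase [BreathPhaseResult-class] for the same recording.
#' @param calib [CalibrationModel-class] for the same recording.
#' @param capnostatMax Capnostat exclusion threshold in units (default 3.5;
#'   readings exceeding it fail).
#' @param calibrantPpmMax Calibrant residual limit in ppm (default 100).
#' @param minCycles Minimum complete respiratory cycles (default 3).
#' @param capnostatStat Summary statistic gating the capnostat criterion,
#'   `"max"` (default) or `"mean"`.
#' @return A [QCReport-class].
#' @export
qcRecording <- function(rec, phase, calib, capnostatMax = 3.5,
                        calibrantPpmMax = 100, minCycles = 3L,
                        capnostatStat = c("max", "mean")) {
  stopifnot(is(rec, "RawRecording"), is(phase, "BreathPhaseResult"),
            is(calib, "CalibrationModel"))
  capnostatStat <- match.arg(capnostatStat)
  capVal <- if (capnostatStat == "max") max(rec@capnostat)
            else mean(rec@capnostat)
  worstPpm <- max(abs(calib@residualPpm))
  capPass <- capVal <= capnostatMax
  calPass <- worstPpm < calibrantPpmMax
  cycPass <- phase@cycleCount >= minCycles
  new("QCReport",
      capnostatPass = capPass, calibrantPass = calPass,
      cyclesPass = cycPass, overallPass = capPass && calPass && cycPass,
      details = list(capnostat_max = capVal, capnostat_limit = capnostatMax,
                     capnostat_stat = capnostatStat,
                     calibrant_worst_ppm = worstPpm,
                     calibrant_limit_ppm = calibrantPpmMax,
                     cycle_count = phase@cycleCount,
                     min_cycles = as.integer(minCycles)))
}
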