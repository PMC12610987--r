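## Feature construction: composite exhalation spectra, peak detection,
## cross-sample alignment, prevalence filtering, internal-standard
## normalization and the modeling exclusion filter.

#' Composite exhalation-phase spectrum
#'
#' Arithmetic mean of the selected (end-tidal) spectra, smoothed along the
#' m/z axis with a Savitzky-Golay filter. Negative smoothing undershoot is
#' clipped at zero.
#'
#' @param rec A [RawRecording-class].
#' @param selectedIndices Time indices of the retained spectra (e.g.
#'   `selectedSpectra(phase)`).
#' @param sgWindow Odd filter window length in grid points (default 7).
#' @param sgOrder Polynomial order, `< sgWindow` (default 3).
#' @return A [SampleSpectrum-class].
#' @export
compositeSpectrum <- function(rec, selectedIndices, sgWindow = 7L,
                              sgOrder = 3L) {
  stopifnot(is(rec, "RawRecording"))
  if (length(selectedIndices) == 0L) stop("no exhalation spectra")
  if (sgOrder >= sgWindow) stop("sgOrder must be smaller than sgWindow")
  if (sgWindow %% 2L == 0L) stop("sgWindow must be odd")
  m <- rec@spectra[selectedIndices, , drop = FALSE]
  comp <- colMeans(m)
  comp <- pmax(.sgSmooth(comp, window = sgWindow, order = sgOrder), 0)
  new("SampleSpectrum", mzAxis = rec@mzAxis, intensity = comp,
      nSpectraUsed = length(selectedIndices),
      provenance = as.integer(selectedIndices))
}

#' Detect peaks in a composite spectrum
#'
#' Local maxima are expanded to the flanking local minima; each peak keeps
#' its intensity-weighted centroid (computed over the contiguous
#' above-half-apex region), apex intensity, and integrated area. Peaks are
#' filtered by an absolute apex floor and by prominence (apex minus the
#' higher flanking minimum) relative to the apex.
#'
#' @param spec A [SampleSpectrum-class].
#' @param minProminenceRel Minimum prominence as a fraction of the apex
#'   (default 0.5; calibrant-scale shoulders survive lower settings).
#' @param minIntensityCps Minimum apex intensity in cps (default 100).
#' @return Data frame with columns `centroid_mz`, `apex_intensity`,
#'   `integrated_area`, `window_lo`, `window_hi`, sorted by centroid;
#'   zero rows when nothing qualifies.
#' @export
detectPeaks <- function(spec, minProminenceRel = 0.5,
                        minIntensityCps = 100) {
  stopifnot(is(spec, "SampleSpectrum"))
  y <- spec@intensity
  mz <- spec@mzAxis
  n <- length(y)
  step <- if (n > 1L) mean(diff(mz)) else 1
  empty <- data.frame(centroid_mz = numeric(0), apex_intensity = numeric(0),
                      integrated_area = numeric(0), window_lo = numeric(0),
                      window_hi = numeric(0))
  if (n < 3L) return(empty)
  isMax <- .localMaxima(y, k = 1L) & y >= minIntensityCps
  apexes <- which(isMax)
  if (!length(apexes)) return(empty)
  rows <- lapply(apexes, function(a) {
    lo <- a; while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
    hi <- a; while (hi < n && y[hi + 1L] < y[hi]) hi <- hi + 1L
    prominence <- y[a] - max(y[lo], y[hi])
    if (prominence < minProminenceRel * y[a]) return(NULL)
    half <- y[a] / 2
    cl <- a; while (cl > lo && y[cl - 1L] >= half) cl <- cl - 1L
    ch <- a; while (ch < hi && y[ch + 1L] >= half) ch <- ch + 1L
    sel <- cl:ch
    data.frame(centroid_mz = sum(mz[sel] * y[sel]) / sum(y[sel]),
               apex_intensity = y[a],
               integrated_area = sum(y[lo:hi]) * step,
               window_lo = mz[lo], window_hi = mz[hi])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out[order(out$centroid_mz), , drop = FALSE]
}

#' Align peak lists across samples into a consensus feature matrix
#'
#' Pools all per-sample peak centroids, sorts them, and clusters by single
#' linkage: a new cluster starts wherever the gap between consecutive
#' centroids exceeds the mass-dependent tolerance ([massTolerance()],
#' +/- 0.015 Da at m/z 42 rising to +/- 0.4 Da at m/z 685). Each cluster's
#' consensus m/z is the median of its member centroids. Clusters detected in
#' more than `minPrevalence` of the samples are retained; missing entries are
#' imputed as 0 (absence = below detection). The procedure is deterministic
#' and invariant to sample order.
#'
#' @param peaklists Named list of per-sample peak data frames from
#'   [detectPeaks()].
#' @param sampleData Optional data frame of per-sample metadata, rows
#'   matching `names(peaklists)`.
#' @param minPrevalence Retention rule: keep features with prevalence
#'   strictly greater than this fraction (default 0.5, i.e. present in over
#'   half of all samples).
#' @param value Which peak quantity fills the matrix: integrated area
#'   (default) or apex intensity.
#' @param tolLow,tolHigh,mzLow,mzHigh Tolerance schedule anchors, passed to
#'   [massTolerance()].
#' @return An un-normalized [BreathFeatureSet-class].
#' @export
alignFeatures <- function(peaklists, sampleData = NULL,
                          minPrevalence = 0.5,
                          value = c("area", "apex"),
                          tolLow = 0.015, tolHigh = 0.4,
                          mzLow = 42, mzHigh = 685) {
  value <- match.arg(value)
  if (length(peaklists) < 2L) stop("alignment requires at least two samples")
  if (is.null(names(peaklists)))
    names(peaklists) <- sprintf("sample%02d", seq_along(peaklists))
  nPeaks <- vapply(peaklists, nrow, integer(1))
  if (all(nPeaks == 0L)) stop("all peak lists are empty")
  valueCol <- if (value == "area") "integrated_area" else "apex_intensity"

  pooled <- do.call(rbind, lapply(names(peaklists), function(s) {
    p <- peaklists[[s]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(sample = s, centroid_mz = p$centroid_mz, val = p[[valueCol]])
  }))
  pooled <- pooled[order(pooled$centroid_mz), , drop = FALSE]
  gapTol <- massTolerance(
    (head(pooled$centroid_mz, -1) + pooled$centroid_mz[-1]) / 2,
    tolLow, tolHigh, mzLow, mzHigh)
  newCluster <- c(TRUE, diff(pooled$centroid_mz) > gapTol)
  pooled$cluster <- cumsum(newCluster)

  samples <- names(peaklists)
  nS <- length(samples)
  clusters <- split(pooled, pooled$cluster)
  consMz <- vapply(clusters, function(cl) median(cl$centroid_mz), numeric(1))
  prev <- vapply(clusters, function(cl)
    length(unique(cl$sample)) / nS, numeric(1))
  keep <- prev > minPrevalence
  if (!any(keep)) stop("no feature passed the prevalence rule")
  clusters <- clusters[keep]
  ord <- order(consMz[keep])
  clusters <- clusters[ord]
  consMz <- consMz[keep][ord]
  prev <- prev[keep][ord]

  vals <- matrix(0, nrow = nS, ncol = length(clusters),
                 dimnames = list(samples, NULL))
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    agg <- tapply(cl$val, cl$sample, sum)  # split peaks in a cluster add up
    vals[names(agg), j] <- agg
  }
  if (!is.null(sampleData)) sampleData <- sampleData[samples, , drop = FALSE]
  BreathFeatureSet(vals, featureMz = as.numeric(consMz),
                   prevalence = as.numeric(prev), sampleData = sampleData,
                   normalized = FALSE)
}

#' Normalize features to the internal standard
#'
#' Divides each sample's feature values by that sample's internal-standard
#' value (the heavy-water isotope adduct at m/z 22.0274 by default), making
#' the matrix invariant to per-sample global intensity scaling. The
#' internal-standard feature itself equals 1 afterwards in every sample where
#' it was detected.
#'
#' @param fm A [BreathFeatureSet-class].
#' @param internalStandardMz Internal standard m/z (default 22.0274).
#' @param tol Match tolerance in Da (default: [massTolerance()] at the
#'   standard's mass).
#' @return The normalized [BreathFeatureSet-class].
#' @export
normalizeFeatures <- function(fm, internalStandardMz = 22.0274, tol = NULL) {
  stopifnot(is(fm, "BreathFeatureSet"))
  mzs <- featureMz(fm)
  if (is.null(tol)) tol <- massTolerance(internalStandardMz)
  d <- abs(mzs - internalStandardMz)
  if (min(d) > tol)
    stop("normalization error: internal standard feature (m/z ",
         internalStandardMz, ") not found within ", tol, " Da")
  isRow <- which.min(d)
  m <- SummarizedExperiment::assay(fm, "intensity")
  std <- m[isRow, ]
  bad <- !is.finite(std) | std <= 0
  if (any(bad))
    stop("normalization error: internal standard missing or zero in ",
         "sample(s): ", paste(colnames(m)[bad], collapse = ", "))
  SummarizedExperiment::assay(fm, "intensity") <- sweep(m, 2, std, "/")
  S4Vectors::metadata(fm)$normalized <- TRUE
  S4Vectors::metadata(fm)$internalStandardMz <- internalStandardMz
  fm
}

#' Exclude calibration ions and low-mass features before modeling
#'
#' Removes features with consensus m/z below `minMz` (default 42) and
#' features within the mass-dependent tolerance of any calibrant ion.
#'
#' @param fm A normalized [BreathFeatureSet-class].
#' @param calibrantMzs Calibrant masses (default the PerMaSCal ions).
#' @param minMz Lower m/z cut-off (default 42).
#' @return The filtered [BreathFeatureSet-class].
#' @export
filterModelFeatures <- function(fm,
                                calibrantMzs = c(21.0220, 203.94299, 330.85),
                                minMz = 42) {
  stopifnot(is(fm, "BreathFeatureSet"))
  if (!isNormalized(fm))
    stop("filterModelFeatures() expects a normalized feature matrix")
  mzs <- featureMz(fm)
  nearCal <- vapply(mzs, function(m)
    any(abs(m - calibrantMzs) <= massTolerance(calibrantMzs)), logical(1))
  keep <- mzs >= minMz & !nearCal
  fm[keep, ]
}
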