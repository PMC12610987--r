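## Shared fixtures: small simulation configs and hand-built objects.

noiseFree <- list(floorCps = 0, shotScale = 0)

## Low-mass acquisition window: covers the internal standard, water adduct
## and the three tracer VOCs; calibrants relocated inside the window.
segRecConfig <- function(seed = 1L, ...) {
  recordingSimConfig(mzRange = c(10, 80),
                     calibrantMzs = c(21.0220, 45.497, 75.5),
                     seed = seed, ...)
}

## Window covering the PerMaSCal calibrants for recalibration tests.
calRecConfig <- function(seed = 1L, ...) {
  recordingSimConfig(mzRange = c(10, 340), durationS = 20, seed = seed, ...)
}

## Standard trace bundle for segmentation.
extractTraces <- function(rec, cfg) {
  list(water = extractEIC(rec, cfg$waterAdductMz),
       tracers = lapply(cfg$tracerChannels$mz, extractEIC, rec = rec))
}

## Hand-built ion trace on an integer time base.
mkTrace <- function(intensity, targetMz = 37.038, window = 0.05) {
  new("IonTrace", targetMz = targetMz, window = window,
      intensity = as.numeric(intensity),
      times = seq_along(intensity) - 1)
}

## Minimal peak list for alignment tests.
mkPeaks <- function(mz, val = rep(1, length(mz))) {
  data.frame(centroid_mz = mz, apex_intensity = val,
             integrated_area = val,
             window_lo = mz - 0.01, window_hi = mz + 0.01)
}

## Feature set built directly from a samples x features matrix.
mkFeatureSet <- function(values, mz, normalized = TRUE,
                         sampleData = NULL) {
  rownames(values) <- rownames(values) %||%
    sprintf("s%02d", seq_len(nrow(values)))
  breathVOC::BreathFeatureSet(values, featureMz = mz,
                              prevalence = rep(1, length(mz)),
                              sampleData = sampleData,
                              normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Tiny flat recording for hand-built spectra.
mkRecording <- function(spectra, mzAxis, capnostat = NULL) {
  RawRecording(mzAxis = mzAxis, spectra = spectra,
               times = seq_len(nrow(spectra)) - 1,
               capnostat = capnostat %||% rep(1, nrow(spectra)),
               metadata = list(subject_id = "T", maneuver = "tidal"))
}

## Gaussian peak sampled on a grid (apex height = amp).
gaussPeak <- function(grid, center, amp, sigma) {
  amp * exp(-0.5 * ((grid - center) / sigma)^2)
}

## Independent brute-force formula oracle over C/H/N/O: full expand.grid
## enumeration with its own plausibility arithmetic, kept deliberately
## separate from the package's depth-first search.
bruteForceFormulas <- function(mass, tolPpm, maxC = 16, maxH = 34,
                               maxN = 3, maxO = 6) {
  am <- atomicMasses()
  g <- expand.grid(C = 0:maxC, H = 0:maxH, N = 0:maxN, O = 0:maxO)
  m <- g$C * am[["C"]] + g$H * am[["H"]] + g$N * am[["N"]] + g$O * am[["O"]]
  keep <- abs(m - mass) <= mass * tolPpm * 1e-6
  g <- g[keep, , drop = FALSE]
  rdbe <- g$C + 1 - g$H / 2 + g$N / 2
  plaus <- rdbe >= 0 & abs(rdbe - round(rdbe)) < 1e-9 &
    g$H <= 2 * g$C + 2 + g$N & (g$C + g$H + g$N + g$O) >= 1
  g <- g[plaus, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  out <- apply(g, 1, function(r) {
    parts <- c(
      if (r[["C"]] > 0) paste0("C", ifelse(r[["C"]] > 1, r[["C"]], "")),
      if (r[["H"]] > 0) paste0("H", ifelse(r[["H"]] > 1, r[["H"]], "")),
      if (r[["N"]] > 0) paste0("N", ifelse(r[["N"]] > 1, r[["N"]], "")),
      if (r[["O"]] > 0) paste0("O", ifelse(r[["O"]] > 1, r[["O"]], "")))
    paste0(parts, collapse = "")
  })
  sort(unname(out))
}
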