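## Synthetic-data module: raw breath recordings and cohort tables with the
## statistical structure the downstream analysis assumes, plus ground truth.

#' Configuration for a simulated PTR-TOF-MS breath recording
#'
#' Defines one sampling session: a dense m/z grid, a raised-cosine breath
#' envelope, exhalation-modulated channels (water adduct, tracer VOCs,
#' internal standard, optional extra channels), constant calibrant channels,
#' a capnostat profile lagging the water signal, Gaussian peak shapes at a
#' configurable TOF resolving power, additive noise, and an optional linear
#' mass-axis drift (every apparent m/z off by `driftPpm` ppm, i.e. an error
#' linear in mass).
#'
#' Channel amplitudes are expressed as integrated extracted-ion-current
#' values (cps summed over the peak) at full exhalation; grid-point
#' intensities follow from the Gaussian peak shape.
#'
#' @param durationS Recording length in seconds (default 60).
#' @param spectraPerS Spectra per second (default 1).
#' @param breathRate Respiratory rate in cycles/minute; the physiological
#'   range emulated is 12-16 (default 14).
#' @param mzRange Acquisition range in Da (default `c(10, 685)`).
#' @param mzStep Grid spacing in Da (default 0.002).
#' @param resolution TOF resolving power m/FWHM (default 2000).
#' @param dutyCycle Fraction of each cycle spent exhaling (default 0.5).
#' @param driftPpm Apparent mass error in ppm applied to every peak position
#'   (default 0).
#' @param noise List with `floorCps` (Gaussian floor SD per grid point, cps)
#'   and `shotScale` (SD multiplier on `sqrt(intensity)`, approximating
#'   counting noise). Default `list(floorCps = 30, shotScale = 1)`.
#' @param tracerChannels Data frame with columns `mz`, `amplitude`,
#'   `baseline` for the exhalation tracer VOCs. Defaults to isoprene
#'   (m/z 69.07), dimethyl sulfide (63.02) and 1,2-butadiene (55.03) at the
#'   instrument's printed target masses.
#' @param waterAdductMz,waterAmplitude,waterBaseline Water adduct channel
#'   (default m/z 37.038, amplitude 2e6, baseline 2e4 cps).
#' @param internalStandardMz,internalStandardAmplitude Heavy-water adduct
#'   internal standard (default m/z 22.0274, amplitude 1e5 cps).
#' @param calibrantMzs,calibrantCps PerMaSCal calibrant ions, constant in
#'   time (default m/z 21.0220, 203.94299, 330.85 at 5e4 cps).
#' @param extraChannels Optional data frame (`mz`, `amplitude`, `baseline`)
#'   of additional exhalation-modulated channels.
#' @param capnostatBaseline,capnostatExcursion,capnostatLagS Capnostat
#'   profile: baseline units, exhalation excursion amplitude, and lag behind
#'   the water adduct in seconds (defaults 0.5, 1.5, 1).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `"RecordingSimConfig"`.
#' @seealso [simulateRecording()]
#' @export
recordingSimConfig <- function(durationS = 60, spectraPerS = 1,
                               breathRate = 14, mzRange = c(10, 685),
                               mzStep = 0.002, resolution = 2000,
                               dutyCycle = 0.5, driftPpm = 0,
                               noise = list(floorCps = 30, shotScale = 1),
                               tracerChannels = data.frame(
                                 mz = c(69.07, 63.02, 55.03),
                                 amplitude = c(5e5, 3e5, 2e5),
                                 baseline = c(1e3, 1e3, 1e3)),
                               waterAdductMz = 37.038,
                               waterAmplitude = 2e6, waterBaseline = 2e4,
                               internalStandardMz = 22.0274,
                               internalStandardAmplitude = 1e5,
                               calibrantMzs = c(21.0220, 203.94299, 330.85),
                               calibrantCps = 5e4,
                               extraChannels = NULL,
                               capnostatBaseline = 0.5,
                               capnostatExcursion = 1.5,
                               capnostatLagS = 1,
                               seed = 1L) {
  cfg <- list(durationS = durationS, spectraPerS = spectraPerS,
              breathRate = breathRate, mzRange = mzRange, mzStep = mzStep,
              resolution = resolution, dutyCycle = dutyCycle,
              driftPpm = driftPpm, noise = noise,
              tracerChannels = tracerChannels,
              waterAdductMz = waterAdductMz,
              waterAmplitude = waterAmplitude,
              waterBaseline = waterBaseline,
              internalStandardMz = internalStandardMz,
              internalStandardAmplitude = internalStandardAmplitude,
              calibrantMzs = calibrantMzs, calibrantCps = calibrantCps,
              extraChannels = extraChannels,
              capnostatBaseline = capnostatBaseline,
              capnostatExcursion = capnostatExcursion,
              capnostatLagS = capnostatLagS,
              seed = as.integer(seed))
  class(cfg) <- "RecordingSimConfig"
  .validateRecordingSimConfig(cfg)
  cfg
}

.validateRecordingSimConfig <- function(cfg) {
  if (!is.numeric(cfg$breathRate) || cfg$breathRate <= 0)
    stop("invalid config: breath_rate must be positive")
  if (cfg$durationS <= 0)
    stop("invalid config: duration must be positive")
  if (cfg$breathRate * cfg$durationS / 60 < 1)
    stop("invalid config: recording must span at least one breath cycle")
  if (cfg$dutyCycle <= 0 || cfg$dutyCycle >= 1)
    stop("invalid config: dutyCycle must lie in (0, 1)")
  allMz <- c(cfg$tracerChannels$mz, cfg$waterAdductMz,
             cfg$internalStandardMz, cfg$calibrantMzs,
             cfg$extraChannels$mz)
  if (any(allMz < cfg$mzRange[1] | allMz > cfg$mzRange[2]))
    stop("invalid config: all configured m/z must lie inside mzRange")
  invisible(TRUE)
}

## Raised-cosine exhalation envelope in [0, 1]; one bump per cycle over the
## exhaled fraction `duty` of each breath period, zero during inhalation.
.breathEnvelope <- function(t, breathRate, duty) {
  period <- 60 / breathRate
  u <- (t %% period) / period
  e <- numeric(length(t))
  inExhale <- u < duty & t >= 0
  e[inExhale] <- 0.5 * (1 - cos(2 * pi * u[inExhale] / duty))
  e
}

#' Simulate a raw breath recording with ground truth
#'
#' Generates a [RawRecording-class] according to a [recordingSimConfig()]:
#' the water adduct, tracer VOCs and internal standard rise during each
#' simulated exhalation with a raised-cosine envelope; calibrant ions are
#' constant; the capnostat channel co-varies with a configurable lag; peaks
#' are Gaussian on the m/z axis; noise is a Gaussian floor plus an
#' intensity-proportional term. Ground truth reports every cycle's index
#' span, the exhalation midpoints, and each channel's true and apparent
#' (drifted) position.
#'
#' @param cfg A `"RecordingSimConfig"` from [recordingSimConfig()].
#' @param subjectId,maneuver Metadata stored in the recording.
#' @return A list with elements `recording` ([RawRecording-class]) and
#'   `groundTruth` (list: `nCycles`, `cycles` data frame with per-cycle index
#'   spans, `exhalationMidpointsS`, `channels` data frame, `envelope`).
#' @export
#' @examples
#' sim <- simulateRecording(recordingSimConfig(mzRange = c(10, 80),
#'                                             durationS = 20, seed = 1))
#' sim$groundTruth$nCycles
simulateRecording <- function(cfg, subjectId = "sim", maneuver = "tidal") {
  if (!inherits(cfg, "RecordingSimConfig"))
    stop("cfg must come from recordingSimConfig()")
  .validateRecordingSimConfig(cfg)
  set.seed(cfg$seed)

  nT <- as.integer(round(cfg$durationS * cfg$spectraPerS))
  t <- (seq_len(nT) - 1L) / cfg$spectraPerS
  grid <- seq(cfg$mzRange[1], cfg$mzRange[2], by = cfg$mzStep)
  env <- .breathEnvelope(t, cfg$breathRate, cfg$dutyCycle)

  channels <- rbind(
    data.frame(mz = cfg$waterAdductMz, amplitude = cfg$waterAmplitude,
               baseline = cfg$waterBaseline, modulated = TRUE,
               role = "water"),
    data.frame(mz = cfg$internalStandardMz,
               amplitude = cfg$internalStandardAmplitude, baseline = 0,
               modulated = TRUE, role = "internal_standard"),
    data.frame(mz = cfg$tracerChannels$mz,
               amplitude = cfg$tracerChannels$amplitude,
               baseline = cfg$tracerChannels$baseline, modulated = TRUE,
               role = "tracer"),
    data.frame(mz = cfg$calibrantMzs, amplitude = cfg$calibrantCps,
               baseline = cfg$calibrantCps, modulated = FALSE,
               role = "calibrant"),
    if (!is.null(cfg$extraChannels))
      data.frame(mz = cfg$extraChannels$mz,
                 amplitude = cfg$extraChannels$amplitude,
                 baseline = cfg$extraChannels$baseline, modulated = TRUE,
                 role = "extra")
  )
  ## apparent (drifted) peak positions: constant-ppm error, linear in mass
  channels$apparentMz <- channels$mz * (1 + cfg$driftPpm * 1e-6)

  sig <- matrix(0, nrow = nT, ncol = length(grid))
  fwhmToSigma <- 2 * sqrt(2 * log(2))
  for (i in seq_len(nrow(channels))) {
    ch <- channels[i, ]
    sigma <- ch$apparentMz / cfg$resolution / fwhmToSigma
    idx <- which(abs(grid - ch$apparentMz) <= 6 * sigma)
    if (!length(idx)) next
    shape <- exp(-0.5 * ((grid[idx] - ch$apparentMz) / sigma)^2)
    shape <- shape * cfg$mzStep / (sigma * sqrt(2 * pi))  # sums to ~1
    timeCourse <- if (ch$modulated) ch$baseline + ch$amplitude * env
                  else rep(ch$amplitude, nT)
    sig[, idx] <- sig[, idx] + outer(timeCourse, shape)
  }

  if (cfg$noise$floorCps > 0 || cfg$noise$shotScale > 0) {
    sd <- sqrt(cfg$noise$floorCps^2 + cfg$noise$shotScale^2 * sig)
    sig <- sig + rnorm(length(sig)) * sd
  }
  sig[sig < 0] <- 0

  capEnv <- .breathEnvelope(t - cfg$capnostatLagS, cfg$breathRate,
                            cfg$dutyCycle)
  capNoiseSd <- if (cfg$noise$floorCps > 0) 0.02 else 0
  cap <- cfg$capnostatBaseline + cfg$capnostatExcursion * capEnv +
    rnorm(nT, sd = capNoiseSd)

  rec <- RawRecording(
    mzAxis = grid, spectra = sig, times = t, capnostat = cap,
    metadata = list(subject_id = subjectId, maneuver = maneuver,
                    acquired_at = "1970-01-01T00:00:00Z",
                    sim_seed = cfg$seed))

  period <- 60 / cfg$breathRate
  nCycles <- as.integer(floor(cfg$durationS / period))
  cycles <- data.frame(cycle = seq_len(nCycles))
  cycles$start_index <- vapply(seq_len(nCycles) - 1L, function(k)
    min(which(t >= k * period)), integer(1))
  cycles$end_index <- vapply(seq_len(nCycles) - 1L, function(k)
    max(which(t < (k + 1) * period)), integer(1))
  midpoints <- (seq_len(nCycles) - 1L) * period + cfg$dutyCycle * period / 2

  list(recording = rec,
       groundTruth = list(nCycles = nCycles, cycles = cycles,
                          exhalationMidpointsS = midpoints,
                          channels = channels, envelope = env))
}

#' Configuration for a simulated cohort
#'
#' Defines a three-group cohort (asthma / COPD / control) with paired tidal
#' and forced breath feature matrices and clinical covariates. Informative
#' m/z channels carry per-group mean shifts (in units of the within-group SD
#' on the log-intensity scale) shared between the two maneuvers; remaining
#' features are pure noise. Bronchodilator-responsive (BDR-positive) asthma
#' and COPD subjects carry elevated FeNO, blood eosinophils and total IgE
#' and shifted BDR-informative VOC channels, and their post-bronchodilator
#' spirometry deltas are drawn to exceed the 10 %-predicted positivity rule.
#'
#' @param nPerGroup Named counts `c(asthma=, copd=, control=)`
#'   (default the study sizes 160/128/254).
#' @param informativeChannels Data frame with columns `mz`, `asthma`,
#'   `copd`, `control`: per-group log-scale mean shifts in SD units. The
#'   default plants group effects on the reported predictor channels
#'   (49.005, 95.054, 79.054, 53.037, 71.055, 77.059, 83.086, 118.071,
#'   44.991, 132.050).
#' @param nNoiseFeatures Number of uninformative channels (default 100).
#' @param bdrEffect List of log-scale shifts (SD units) applied to
#'   BDR-positive subjects: `feno`, `eos`, `ige`, and `voc` (a data frame
#'   `mz`/`shift`, default channels 79.054 and 101.039). Set all to zero for
#'   a null cohort.
#' @param bdrRate Named positive-BDR prevalence in asthma and COPD
#'   (default `c(asthma = 0.701, copd = 0.455)`, the study's rates).
#' @param missingRate Fraction of FeNO/eosinophil/IgE values set missing
#'   (default 0.02).
#' @param subjectSd,noiseSd Log-scale SD of the shared per-subject effect
#'   and of the maneuver-specific residual (defaults 0.6, 0.8; shifts are
#'   expressed in units of their pooled SD, 1.0).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `"CohortSimConfig"`.
#' @export
cohortSimConfig <- function(nPerGroup = c(asthma = 160, copd = 128,
                                          control = 254),
                            informativeChannels = data.frame(
                              mz = c(49.005, 95.054, 79.054, 53.037, 71.055,
                                     77.059, 83.086, 118.071, 44.991,
                                     132.050),
                              asthma = c(1.0, 1.0, 0.3, 0.2, 0.2,
                                         0.0, 0.0, 0.0, 0.8, 0.8),
                              copd = c(0.0, 0.2, 1.0, 1.0, 1.0,
                                       0.8, 0.8, 0.8, 0.8, 0.0),
                              control = rep(0, 10)),
                            nNoiseFeatures = 100,
                            bdrEffect = list(
                              feno = 0.8, eos = 0.7, ige = 0.6,
                              voc = data.frame(mz = c(79.054, 101.039),
                                               shift = c(0.8, 0.8))),
                            bdrRate = c(asthma = 0.701, copd = 0.455),
                            missingRate = 0.02,
                            subjectSd = 0.6, noiseSd = 0.8,
                            seed = 1L) {
  cfg <- list(nPerGroup = nPerGroup,
              informativeChannels = informativeChannels,
              nNoiseFeatures = nNoiseFeatures, bdrEffect = bdrEffect,
              bdrRate = bdrRate, missingRate = missingRate,
              subjectSd = subjectSd, noiseSd = noiseSd,
              seed = as.integer(seed))
  class(cfg) <- "CohortSimConfig"
  .validateCohortSimConfig(cfg)
  cfg
}

.validateCohortSimConfig <- function(cfg) {
  if (sum(cfg$nPerGroup) == 0)
    stop("invalid config: at least one group must be non-empty")
  if (any(cfg$nPerGroup < 0))
    stop("invalid config: group sizes must be non-negative")
  if (!all(is.finite(as.matrix(
        cfg$informativeChannels[c("asthma", "copd", "control")]))))
    stop("invalid config: group mean shifts must be finite")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("invalid config: missingRate must lie in [0, 1)")
  invisible(TRUE)
}

#' Simulate a cohort with paired tidal/forced feature matrices
#'
#' @param cfg A `"CohortSimConfig"` from [cohortSimConfig()].
#' @return A list with elements `cohort` (data frame of clinical covariates
#'   and the `bdr` label), `features` (list of two
#'   [BreathFeatureSet-class] objects, `tidal` and `forced`, sharing the
#'   planted signal), and `groundTruth` (informative channel table and the
#'   BDR-informative channels).
#' @export
#' @examples
#' sim <- simulateCohort(cohortSimConfig(
#'   nPerGroup = c(asthma = 10, copd = 10, control = 10), seed = 1))
#' table(sim$cohort$group, sim$cohort$bdr, useNA = "ifany")
simulateCohort <- function(cfg) {
  if (!inherits(cfg, "CohortSimConfig"))
    stop("cfg must come from cohortSimConfig()")
  .validateCohortSimConfig(cfg)
  set.seed(cfg$seed)

  groups <- rep(names(cfg$nPerGroup), times = cfg$nPerGroup)
  n <- length(groups)
  id <- sprintf("S%03d", seq_len(n))

  ## --- BDR status and clinical covariates -------------------------------
  bdr <- rep(NA_character_, n)
  for (g in c("asthma", "copd")) {
    sel <- groups == g
    if (any(sel))
      bdr[sel] <- ifelse(rbinom(sum(sel), 1, cfg$bdrRate[[g]]) == 1,
                         "positive", "negative")
  }
  bdrPos <- !is.na(bdr) & bdr == "positive"

  dFev1 <- ifelse(bdrPos, runif(n, 10.3, 30), runif(n, -5, 9.7))
  dFev1[groups == "control"] <- NA_real_
  dFvc <- runif(n, -5, 9.7)
  dFvc[groups == "control"] <- NA_real_

  lmean <- function(ctrl, asth, copd)
    log(c(control = ctrl, asthma = asth, copd = copd))[groups]
  feno <- exp(lmean(15, 30, 18) + 0.5 * cfg$bdrEffect$feno * bdrPos +
                rnorm(n, sd = 0.5))
  eos <- exp(lmean(0.15, 0.25, 0.18) + 0.5 * cfg$bdrEffect$eos * bdrPos +
               rnorm(n, sd = 0.5))
  ige <- exp(lmean(50, 150, 80) + 1.0 * cfg$bdrEffect$ige * bdrPos +
               rnorm(n, sd = 1))
  fev1 <- c(control = 98, asthma = 85, copd = 55)[groups] +
    rnorm(n, sd = c(control = 10, asthma = 15, copd = 18)[groups])
  fvc <- c(control = 100, asthma = 95, copd = 80)[groups] +
    rnorm(n, sd = 12)
  smokingLevels <- c("never", "former", "current")
  smokeP <- rbind(control = c(0.60, 0.25, 0.15),
                  asthma = c(0.70, 0.20, 0.10),
                  copd = c(0.10, 0.55, 0.35))
  smoking <- vapply(groups, function(g)
    sample(smokingLevels, 1, prob = smokeP[g, ]), character(1))
  bmi <- rnorm(n, 26, 4)

  if (cfg$missingRate > 0)
    for (v in c("feno", "eos", "ige")) {
      miss <- runif(n) < cfg$missingRate
      assign(v, replace(get(v), miss, NA_real_))
    }

  cohort <- data.frame(
    subject_id = id, group = groups,
    fev1_pct_pred = fev1, fvc_pct_pred = fvc,
    delta_fev1_pct_pred = dFev1, delta_fvc_pct_pred = dFvc,
    feno_ppb = feno, eos_10e9_l = eos, ige_iu_ml = ige,
    smoking = smoking, bmi = bmi, bdr = bdr,
    stringsAsFactors = FALSE)

  ## --- feature matrices --------------------------------------------------
  info <- cfg$informativeChannels
  bdrVoc <- cfg$bdrEffect$voc
  extraBdrMz <- setdiff(round(bdrVoc$mz, 4), round(info$mz, 4))
  noiseMz <- sort(runif(cfg$nNoiseFeatures, 42.5, 250))
  ## keep noise channels clear of planted ones
  planted <- c(info$mz, extraBdrMz)
  for (m in planted) noiseMz <- noiseMz[abs(noiseMz - m) > 0.5]
  featMz <- sort(c(info$mz, extraBdrMz, noiseMz))
  nF <- length(featMz)
  totalSd <- sqrt(cfg$subjectSd^2 + cfg$noiseSd^2)

  baseLog <- runif(nF, -1, 1)            # per-feature baseline level
  shift <- matrix(0, n, nF)              # planted log-scale shifts
  colIdx <- function(m) which(abs(featMz - m) < 1e-6)
  for (i in seq_len(nrow(info))) {
    j <- colIdx(info$mz[i])
    shift[, j] <- shift[, j] +
      totalSd * as.numeric(info[i, groups])
  }
  for (i in seq_len(nrow(bdrVoc))) {
    j <- colIdx(bdrVoc$mz[i])
    shift[bdrPos, j] <- shift[bdrPos, j] + totalSd * bdrVoc$shift[i]
  }

  subjEff <- matrix(rnorm(n * nF, sd = cfg$subjectSd), n, nF)
  mkMatrix <- function() {
    eps <- matrix(rnorm(n * nF, sd = cfg$noiseSd), n, nF)
    exp(sweep(shift + subjEff + eps, 2, baseLog, "+"))
  }
  sampleData <- function(maneuver) data.frame(
    subject_id = id, maneuver = maneuver, group = groups, bdr = bdr,
    row.names = paste(id, maneuver, sep = "_"), stringsAsFactors = FALSE)
  mkSet <- function(maneuver) {
    v <- mkMatrix()
    rownames(v) <- paste(id, maneuver, sep = "_")
    BreathFeatureSet(v, featureMz = featMz,
                     prevalence = rep(1, nF),
                     sampleData = sampleData(maneuver),
                     normalized = TRUE)
  }
  features <- list(tidal = mkSet("tidal"), forced = mkSet("forced"))

  list(cohort = cohort, features = features,
       groundTruth = list(informativeChannels = info,
                          bdrChannels = bdrVoc,
                          featureMz = featMz))
}
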