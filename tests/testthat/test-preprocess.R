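test_that("recalibration corrects a 50 ppm drifted axis within tolerance", {
  sim <- simulateRecording(calRecConfig(seed = 1, driftPpm = 50,
                                        noise = noiseFree))
  cal <- recalibrate(sim$recording)
  expect_lt(max(abs(residualPpm(cal$model))), 100)

  ## idempotence: recalibrating the corrected recording barely moves it
  cal2 <- recalibrate(cal$recording)
  expect_lt(max(abs(residualPpm(cal2$model) - residualPpm(cal$model))), 1)
})

test_that("zero drift yields an identity correction", {
  sim <- simulateRecording(calRecConfig(seed = 2, driftPpm = 0,
                                        noise = noiseFree))
  cal <- recalibrate(sim$recording)
  ppmShift <- abs(mzAxis(cal$recording) - mzAxis(sim$recording)) /
    mzAxis(sim$recording) * 1e6
  expect_lt(max(ppmShift), 1)
  expect_lt(max(abs(residualPpm(cal$model))), 1)
})

test_that("an absent reference peak raises a calibration error naming it", {
  sim <- simulateRecording(calRecConfig(seed = 3))
  expect_error(
    recalibrate(sim$recording, referenceMzs = c(21.0220, 203.94299, 310.0)),
    "310")
})

test_that("EIC extraction is linear and respects the axis range", {
  grid <- seq(60, 80, by = 0.005)
  zero <- mkRecording(matrix(0, 5, length(grid)), grid)
  tr <- extractEIC(zero, 69.07)
  expect_true(all(tr@intensity == 0))

  sim <- simulateRecording(segRecConfig(seed = 5, durationS = 15))
  rec <- sim$recording
  doubled <- RawRecording(mzAxis(rec), spectra(rec) * 2, acqTimes(rec),
                          capnostat(rec), rec@metadata)
  expect_equal(extractEIC(doubled, 69.07)@intensity,
               2 * extractEIC(rec, 69.07)@intensity)
  expect_error(extractEIC(rec, 9.99), "range error")
  expect_error(extractEIC(rec, 80.01), "range error")
})

test_that("segmentation recovers the ground-truth cycle count without noise", {
  cfg <- segRecConfig(seed = 1, noise = noiseFree)
  sim <- simulateRecording(cfg)
  tr <- extractTraces(sim$recording, cfg)
  ph <- segmentBreaths(tr$water, tr$tracers)
  expect_identical(cycleCount(ph), sim$groundTruth$nCycles)
  ## selected spectra lie inside water-above-threshold runs
  expect_true(all(ph@flags$water_ok[selectedSpectra(ph)]))
})

test_that("segmentation follows the water-threshold and tracer-coincidence rules", {
  ## constant water below threshold: nothing selected, zero cycles
  low <- mkTrace(rep(1e4, 20))
  bump <- rep(0, 20); bump[c(5, 12)] <- 100
  tracers <- list(mkTrace(bump, 69.07), mkTrace(bump, 63.02),
                  mkTrace(bump, 55.03))
  ph <- segmentBreaths(low, tracers)
  expect_identical(cycleCount(ph), 0L)
  expect_length(selectedSpectra(ph), 0)

  ## water high but only one tracer peaking: spectrum not selected
  high <- mkTrace(rep(3e5, 20))
  flat <- mkTrace(rep(1, 20))
  ph1 <- segmentBreaths(high, list(mkTrace(bump, 69.07), flat, flat))
  expect_length(selectedSpectra(ph1), 0)
  ## two of three tracers peaking: selected at the coincidence window
  ph2 <- segmentBreaths(high, list(mkTrace(bump, 69.07),
                                   mkTrace(bump, 63.02), flat))
  expect_true(all(c(5, 12) %in% selectedSpectra(ph2)))

  expect_error(segmentBreaths(mkTrace(rep(1, 10)),
                              list(mkTrace(rep(1, 9)))),
               "time base")
})

test_that("lowering the water threshold never shrinks the selected set", {
  for (s in 1:3) {
    cfg <- segRecConfig(seed = s)
    sim <- simulateRecording(cfg)
    tr <- extractTraces(sim$recording, cfg)
    hi <- selectedSpectra(segmentBreaths(tr$water, tr$tracers, 2e5))
    lo <- selectedSpectra(segmentBreaths(tr$water, tr$tracers, 1e5))
    expect_true(all(hi %in% lo))
  }
})

test_that("QC criteria flag capnostat, calibration and cycle failures", {
  cfg <- segRecConfig(seed = 6, durationS = 20)
  sim <- simulateRecording(cfg)
  cal <- recalibrate(sim$recording, cfg$calibrantMzs)
  tr <- extractTraces(cal$recording, cfg)
  ph <- segmentBreaths(tr$water, tr$tracers)
  qc <- qcRecording(cal$recording, ph, cal$model)
  expect_true(qc@capnostatPass && qc@calibrantPass && qc@cyclesPass)
  expect_true(overallPass(qc))

  ## capnostat reading of 3.6 exceeds the 3.5-unit limit
  hot <- RawRecording(mzAxis(cal$recording), spectra(cal$recording),
                      acqTimes(cal$recording),
                      replace(capnostat(cal$recording), 1, 3.6),
                      cal$recording@metadata)
  qcHot <- qcRecording(hot, ph, cal$model)
  expect_false(qcHot@capnostatPass)
  expect_false(overallPass(qcHot))

  ## two cycles are fewer than the required three
  few <- new("BreathPhaseResult", selected = selectedSpectra(ph)[1:2],
             cycleCount = 2L, flags = ph@flags)
  qcFew <- qcRecording(cal$recording, few, cal$model)
  expect_false(qcFew@cyclesPass)
  expect_false(overallPass(qcFew))
})
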