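test_that("simulated recording honors the configured cycle count and is deterministic", {
  sim <- simulateRecording(segRecConfig(seed = 1, breathRate = 14,
                                        durationS = 60))
  expect_equal(sim$groundTruth$nCycles, 14L)
  expect_equal(nrow(spectra(sim$recording)), 60L)

  a <- simulateRecording(segRecConfig(seed = 7))
  b <- simulateRecording(segRecConfig(seed = 7))
  expect_identical(spectra(a$recording), spectra(b$recording))
  expect_identical(capnostat(a$recording), capnostat(b$recording))
  c <- simulateRecording(segRecConfig(seed = 8))
  expect_false(identical(spectra(a$recording), spectra(c$recording)))
})

test_that("noise-free tracer EICs peak at the true exhalation midpoints", {
  cfg <- segRecConfig(seed = 1, noise = noiseFree, durationS = 30)
  sim <- simulateRecording(cfg)
  gt <- sim$groundTruth
  iso <- extractEIC(sim$recording, 69.07)
  for (k in seq_len(gt$nCycles)) {
    span <- gt$cycles$start_index[k]:gt$cycles$end_index[k]
    tMax <- iso@times[span][which.max(iso@intensity[span])]
    ## the sampled maximum is the grid point nearest the envelope midpoint
    expect_lte(abs(tMax - gt$exhalationMidpointsS[k]), 0.51)
  }
})

test_that("invalid recording configs are rejected", {
  expect_error(recordingSimConfig(breathRate = 0), "breath_rate")
  expect_error(recordingSimConfig(breathRate = -2), "breath_rate")
  expect_error(recordingSimConfig(durationS = 2), "at least one breath")
  expect_error(recordingSimConfig(mzRange = c(10, 30)), "inside mzRange")
})

test_that("a planted cohort channel separates the groups", {
  cfg <- cohortSimConfig(
    nPerGroup = c(asthma = 30, copd = 0, control = 30),
    informativeChannels = data.frame(mz = 79.054, asthma = 2,
                                     copd = 0, control = 0),
    bdrEffect = list(feno = 0, eos = 0, ige = 0,
                     voc = data.frame(mz = 101.039, shift = 0)),
    nNoiseFeatures = 20, seed = 11)
  sim <- simulateCohort(cfg)
  fs <- sim$features$tidal
  j <- which.min(abs(featureMz(fs) - 79.054))
  x <- log(intensityMatrix(fs)[, j])
  g <- as.data.frame(SummarizedExperiment::colData(fs))$group
  p <- stats::t.test(x ~ g)$p.value
  expect_lt(p, 0.05)
})

test_that("null cohorts are exchangeable and generation is deterministic", {
  nullCfg <- function(seed) cohortSimConfig(
    nPerGroup = c(asthma = 25, copd = 0, control = 25),
    informativeChannels = data.frame(mz = 79.054, asthma = 0,
                                     copd = 0, control = 0),
    bdrEffect = list(feno = 0, eos = 0, ige = 0,
                     voc = data.frame(mz = 101.039, shift = 0)),
    nNoiseFeatures = 10, missingRate = 0, seed = seed)
  sim <- simulateCohort(nullCfg(5))
  fs <- sim$features$forced
  g <- as.data.frame(SummarizedExperiment::colData(fs))$group
  ## no channel should separate the groups beyond chance
  p <- apply(log(intensityMatrix(fs)), 2, function(x)
    stats::wilcox.test(x ~ g, exact = FALSE)$p.value)
  expect_gt(min(stats::p.adjust(p, "bonferroni")), 0.05)

  again <- simulateCohort(nullCfg(5))
  expect_identical(sim$cohort, again$cohort)
  expect_identical(intensityMatrix(sim$features$tidal),
                   intensityMatrix(again$features$tidal))

  expect_error(simulateCohort(cohortSimConfig(
    nPerGroup = c(asthma = 0, copd = 0, control = 0))), "non-empty")
})

test_that("BDR-positive subjects carry elevated clinical biomarkers", {
  sim <- simulateCohort(cohortSimConfig(
    nPerGroup = c(asthma = 60, copd = 60, control = 10),
    missingRate = 0, seed = 3))
  co <- sim$cohort[sim$cohort$group != "control", ]
  expect_true(all(co$bdr %in% c("positive", "negative")))
  expect_gt(median(co$feno_ppb[co$bdr == "positive"]),
            median(co$feno_ppb[co$bdr == "negative"]))
  ## deltas are consistent with the labeling rule
  expect_identical(unname(labelBDR(co$delta_fev1_pct_pred,
                                   co$delta_fvc_pct_pred)), co$bdr)
})
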