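test_that("composite spectrum is the smoothed mean of the selection", {
  grid <- seq(60, 80, by = 0.005)
  one <- gaussPeak(grid, 69.07, 1000, 0.015)
  rec <- mkRecording(rbind(one, one, one), grid)

  comp <- compositeSpectrum(rec, 1:3)
  single <- compositeSpectrum(rec, 1L)
  expect_equal(comp@intensity, single@intensity)
  expect_identical(single@nSpectraUsed, 1L)
  expect_identical(comp@nSpectraUsed, 3L)
  expect_identical(mzAxis(comp), grid)

  expect_error(compositeSpectrum(rec, integer(0)), "no exhalation spectra")
  expect_error(compositeSpectrum(rec, 1:2, sgWindow = 5, sgOrder = 5),
               "smaller")
})

test_that("smoothing moves a noise-free Gaussian apex by less than one grid step", {
  grid <- seq(60, 80, by = 0.005)
  peak <- gaussPeak(grid, 69.07, 1000, 0.015)
  rec <- mkRecording(matrix(peak, nrow = 1), grid)
  comp <- compositeSpectrum(rec, 1L)
  apexBefore <- grid[which.max(peak)]
  apexAfter <- grid[which.max(comp@intensity)]
  expect_lt(abs(apexAfter - apexBefore), 0.005)
})

test_that("peak detection finds centroids and is scale invariant", {
  grid <- seq(40, 120, by = 0.005)
  y <- gaussPeak(grid, 69.07, 2000, 0.017) + gaussPeak(grid, 95.05, 800, 0.024)
  rec <- mkRecording(matrix(y, nrow = 1), grid)
  pk <- detectPeaks(compositeSpectrum(rec, 1L))
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$centroid_mz[1] - 69.07), 0.005)
  expect_lt(abs(pk$centroid_mz[2] - 95.05), 0.005)

  flat <- detectPeaks(compositeSpectrum(
    mkRecording(matrix(50, nrow = 1, ncol = length(grid)), grid), 1L))
  expect_equal(nrow(flat), 0L)

  rec2 <- mkRecording(matrix(2 * y, nrow = 1), grid)
  pk2 <- detectPeaks(compositeSpectrum(rec2, 1L))
  expect_equal(pk2$centroid_mz, pk$centroid_mz)
  expect_equal(pk2$integrated_area, 2 * pk$integrated_area)
})

test_that("alignment merges within tolerance and applies the prevalence rule", {
  pls <- list(a = mkPeaks(c(100.000, 60.0), c(5, 1)),
              b = mkPeaks(c(100.010, 60.004), c(7, 2)))
  fm <- alignFeatures(pls)
  expect_equal(nrow(fm), 2L)
  expect_equal(prevalence(fm), c(1, 1))
  expect_equal(featureMz(fm)[2], 100.005)

  ## present in 2 of 5 samples: dropped by the >50% rule
  pls5 <- list(a = mkPeaks(c(60, 100)), b = mkPeaks(c(60, 100)),
               c = mkPeaks(60), d = mkPeaks(60), e = mkPeaks(60))
  fm5 <- alignFeatures(pls5)
  expect_equal(nrow(fm5), 1L)
  expect_equal(featureMz(fm5), 60)
  ## zero-imputation leaves absent entries at 0
  expect_true(all(intensityMatrix(fm5) == 1))

  expect_error(alignFeatures(pls[1]), "two samples")
  expect_error(alignFeatures(list(a = mkPeaks(numeric(0)),
                                  b = mkPeaks(numeric(0)))), "empty")
})

test_that("alignment is invariant to sample order", {
  set.seed(42)
  pls <- lapply(1:6, function(i)
    mkPeaks(sort(c(60 + rnorm(1, sd = 0.002), 80 + rnorm(1, sd = 0.002),
                   100 + rnorm(1, sd = 0.002))), runif(3, 1, 10)))
  names(pls) <- letters[1:6]
  f1 <- alignFeatures(pls)
  f2 <- alignFeatures(rev(pls))
  expect_equal(featureMz(f1), featureMz(f2))
  expect_equal(intensityMatrix(f1)[letters[1:6], ],
               intensityMatrix(f2)[letters[1:6], ])
})

test_that("internal-standard normalization cancels per-sample scaling", {
  vals <- rbind(c(4, 2, 8), c(2, 5, 1))
  fm <- mkFeatureSet(vals, mz = c(22.0274, 69.07, 95.05),
                     normalized = FALSE)
  nm <- normalizeFeatures(fm)
  expect_true(isNormalized(nm))
  m <- intensityMatrix(nm)
  expect_equal(unname(m[1, ]), c(1, 0.5, 2))  # standard 4, feature 2 -> 0.5
  expect_equal(unname(m[, 1]), c(1, 1))       # standard itself becomes 1

  scaled <- mkFeatureSet(rbind(vals[1, ] * 2, vals[2, ]),
                         mz = c(22.0274, 69.07, 95.05), normalized = FALSE)
  expect_equal(intensityMatrix(normalizeFeatures(scaled)),
               intensityMatrix(nm))

  zero <- mkFeatureSet(rbind(c(0, 2, 8)), mz = c(22.0274, 69.07, 95.05),
                       normalized = FALSE)
  expect_error(normalizeFeatures(zero), "missing or zero")
  noIS <- mkFeatureSet(vals, mz = c(50, 69.07, 95.05), normalized = FALSE)
  expect_error(normalizeFeatures(noIS), "not found")
})

test_that("model filter removes calibration ions and sub-42 features", {
  fm <- mkFeatureSet(matrix(1, 2, 5),
                     mz = c(21.022, 44.991, 69.07, 203.943, 330.85))
  kept <- featureMz(filterModelFeatures(fm))
  expect_equal(kept, c(44.991, 69.07))

  raw <- mkFeatureSet(matrix(1, 2, 2), mz = c(44.991, 69.07),
                      normalized = FALSE)
  expect_error(filterModelFeatures(raw), "normalized")
})
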