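test_that("recording bundles round-trip losslessly", {
  sim <- simulateRecording(segRecConfig(seed = 2, durationS = 15))
  rec <- sim$recording
  path <- withr::local_tempdir()
  bundle <- file.path(path, "rec")
  writeRecording(rec, bundle)
  back <- readRecording(bundle)
  expect_identical(mzAxis(back), mzAxis(rec))
  expect_identical(spectra(back), unname(spectra(rec)))
  expect_identical(acqTimes(back), acqTimes(rec))
  expect_identical(capnostat(back), capnostat(rec))
  expect_identical(back@metadata$subject_id, rec@metadata$subject_id)
  expect_identical(back@metadata$maneuver, rec@metadata$maneuver)

  expect_error(writeRecording(rec, bundle), "already exists")
  expect_silent(writeRecording(rec, bundle, overwrite = TRUE))
})

test_that("missing mandatory bundle members raise format errors", {
  sim <- simulateRecording(segRecConfig(seed = 2, durationS = 5))
  path <- withr::local_tempdir()
  bundle <- file.path(path, "rec")
  writeRecording(sim$recording, bundle)
  file.remove(file.path(bundle, "capnostat.txt"))
  expect_error(readRecording(bundle), "capnostat.*missing")
  expect_error(readRecording(file.path(path, "nowhere")), "no recording")
})

test_that("unknown bundle members are ignored with a warning", {
  sim <- simulateRecording(segRecConfig(seed = 2, durationS = 5))
  path <- withr::local_tempdir()
  bundle <- file.path(path, "rec")
  writeRecording(sim$recording, bundle)
  writeLines("extra", file.path(bundle, "vendor_notes.txt"))
  expect_warning(back <- readRecording(bundle), "vendor_notes")
  expect_identical(mzAxis(back), mzAxis(sim$recording))
})

test_that("invalid recordings are rejected before write", {
  expect_error(RawRecording(mzAxis = 1:3, spectra = matrix(0, 0, 3),
                            times = numeric(0), capnostat = numeric(0)),
               "no spectra")
  expect_error(RawRecording(mzAxis = c(2, 1), spectra = matrix(0, 1, 2),
                            times = 0, capnostat = 0),
               "strictly increasing")
  expect_error(RawRecording(mzAxis = c(1, 2), spectra = matrix(-1, 1, 2),
                            times = 0, capnostat = 0),
               "non-negative")
})

test_that("a simulated one-minute session yields sixty spectra on disk", {
  sim <- simulateRecording(segRecConfig(seed = 4, durationS = 60))
  path <- withr::local_tempdir()
  bundle <- file.path(path, "rec")
  writeRecording(sim$recording, bundle)
  expect_equal(nrow(spectra(readRecording(bundle))), 60L)
})
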