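## Small planted-signal cohort used across the modeling tests.
plantedCohort <- function(seed, nPer = 40, shift = 2, nNoise = 50) {
  simulateCohort(cohortSimConfig(
    nPerGroup = c(asthma = nPer, copd = 0, control = nPer),
    informativeChannels = data.frame(mz = 79.054, asthma = shift,
                                     copd = 0, control = 0),
    bdrEffect = list(feno = 0, eos = 0, ige = 0,
                     voc = data.frame(mz = 101.039, shift = 0)),
    nNoiseFeatures = nNoise, missingRate = 0, seed = seed))
}

groupsOf <- function(fs)
  as.data.frame(SummarizedExperiment::colData(fs))$group

test_that("stratified splitting keeps per-class proportions and is seeded", {
  d <- data.frame(cls = rep(c("a", "b"), each = 50))
  sp <- splitData(d, "cls", 0.7, seed = 4)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_equal(unname(table(d$cls[sp$train])), c(35L, 35L),
               ignore_attr = TRUE)
  expect_setequal(c(sp$train, sp$test), 1:100)

  sp2 <- splitData(d, "cls", 0.7, seed = 4)
  expect_identical(sp, sp2)

  single <- data.frame(cls = c("a", rep("b", 9)))
  expect_error(splitData(single, "cls"), "split error")
})

test_that("resampling importance ranks a planted feature first", {
  sim <- plantedCohort(seed = 21)
  fs <- sim$features$forced
  y <- factor(groupsOf(fs), c("control", "asthma"))
  imp <- resampleImportance(fs, y, nIter = 60, seed = 1)
  expect_equal(names(which.max(imp)), "79.0540")

  imp2 <- resampleImportance(fs, y, nIter = 60, seed = 1)
  expect_identical(imp, imp2)
  expect_error(resampleImportance(fs, y, nIter = 0), "config error")
})

test_that("permuting the labels destroys the planted feature's selection advantage", {
  sim <- plantedCohort(seed = 22, shift = 2, nNoise = 30)
  fs <- sim$features$forced
  X <- intensityMatrix(fs)
  colnames(X) <- sprintf("%.4f", featureMz(fs))
  y <- factor(groupsOf(fs), c("control", "asthma"))

  topFreq <- function(labels, seed, nIter = 40, k = 5) {
    set.seed(seed)
    n <- nrow(X); m <- round(2 / 3 * n)
    freq <- setNames(numeric(ncol(X)), colnames(X))
    for (i in seq_len(nIter)) {
      idx <- sample(n, m)
      imp <- resampleImportance(X[idx, ], labels[idx], nIter = 1,
                                nrounds = 20, seed = i)
      top <- names(imp)[order(-imp)][seq_len(k)]
      top <- top[imp[top] > 0]  # zero-importance ties carry no evidence
      freq[top] <- freq[top] + 1
    }
    freq / nIter
  }
  freqTrue <- topFreq(y, seed = 11)
  set.seed(99)
  freqPerm <- topFreq(sample(y), seed = 11)
  ## with real labels the planted channel is selected essentially always,
  ## under permutation it falls back into the noise band
  expect_gt(freqTrue[["79.0540"]], 0.9)
  expect_gt(freqTrue[["79.0540"]], max(freqPerm))
})

test_that("consensus selection truncates, intersects and breaks ties by m/z", {
  imp <- setNames(c(5, 4, 3, 2, 1), sprintf("%.4f", c(50, 60, 70, 80, 90)))
  sel <- consensusFeatureSelection(list(forced = imp, tidal = imp),
                                   topK = 3)
  expect_length(consensusFeatures(sel), 3)
  expect_identical(sel@rankedLists$forced,
                   sprintf("%.4f", c(50, 60, 70)))

  ## tie between 80 and 60 resolved toward the lower m/z
  tied <- setNames(c(1, 2, 2, 5), sprintf("%.4f", c(50, 80, 60, 70)))
  selT <- consensusFeatureSelection(list(a = tied, b = tied), topK = 2)
  expect_identical(selT@rankedLists$a, sprintf("%.4f", c(70, 60)))

  other <- setNames(c(1, 2, 3, 4, 5), names(imp))
  expect_warning(
    empty <- consensusFeatureSelection(list(forced = imp, tidal = other),
                                       topK = 2),
    "empty")
  expect_length(consensusFeatures(empty), 0)

  ## the top-percent alternative controls the truncation depth
  selP <- consensusFeatureSelection(list(forced = imp, tidal = imp),
                                    topPercent = 0.4)
  expect_identical(selP@topK, 2L)
})

test_that("planted features reach the consensus across both maneuvers", {
  sim <- plantedCohort(seed = 23, nNoise = 30)
  ys <- lapply(sim$features, function(fs)
    factor(groupsOf(fs), c("control", "asthma")))
  sel <- selectConsensusFeatures(sim$features, ys, topK = 10, nIter = 40,
                                 seed = 2)
  expect_true("79.0540" %in% consensusFeatures(sel))
  expect_true(all(lengths(sel@rankedLists) <= 10))
})

test_that("tuning finds a separable configuration and is deterministic", {
  set.seed(5)
  ## two classes separated by a wide margin on the first feature
  x1 <- c(runif(30, -2, -1), runif(30, 1, 2))
  X <- cbind(a = sample(x1), b = rnorm(60))
  y <- factor(ifelse(X[, "a"] > 0, "pos", "neg"), c("neg", "pos"))
  fit <- tuneAndFit(X, y, seed = 3)
  expect_equal(fit$cvAUC, 1.0)
  fit2 <- tuneAndFit(X, y, seed = 3)
  expect_identical(fit$bestParams, fit2$bestParams)

  rep <- evaluateModel(fit, X, y, scheme = "holdout")
  expect_equal(rep@auc, 1.0)
  expect_equal(rep@sensitivity, 1.0)
  expect_equal(rep@specificity, 1.0)
})

test_that("LOO evaluation recovers a strong planted BDR-style signal", {
  sim <- plantedCohort(seed = 24, nPer = 30, shift = 2.5, nNoise = 10)
  fs <- sim$features$forced
  y <- factor(groupsOf(fs), c("control", "asthma"))
  X <- intensityMatrix(fs)
  colnames(X) <- sprintf("%.4f", featureMz(fs))
  fit <- tuneAndFit(X, y, cvFolds = 3, seed = 6)
  rep <- evaluateModel(fit, X, y, scheme = "loo", endpoint = "bdr")
  expect_gt(rep@auc, 0.9)
  expect_identical(rep@cvScheme, "loo")
  expect_error(evaluateModel(fit, X, factor(rep("a", nrow(X)))),
               "single class")
})

test_that("feature selection never sees held-out samples", {
  sim <- plantedCohort(seed = 25, nPer = 30, nNoise = 20)
  fs <- sim$features$forced
  y <- factor(groupsOf(fs), c("control", "asthma"))
  X <- intensityMatrix(fs)
  sp <- splitData(data.frame(cls = y), "cls", 0.7, seed = 9)
  impA <- resampleImportance(X[sp$train, ], y[sp$train], nIter = 25,
                             seed = 3)
  ## corrupting the held-out rows must not change train-only selection
  X2 <- X
  X2[sp$test, ] <- 0
  impB <- resampleImportance(X2[sp$train, ], y[sp$train], nIter = 25,
                             seed = 3)
  expect_identical(impA, impB)
})
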