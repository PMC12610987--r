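## Modeling machinery: stratified splitting, resampling-consensus feature
## selection with gradient boosting, cross-validated tuning, and threshold
## metrics.

.asFeatureMatrix <- function(X) {
  if (is(X, "BreathFeatureSet")) {
    m <- intensityMatrix(X)
    colnames(m) <- sprintf("%.4f", featureMz(X))
    m
  } else as.matrix(X)
}

.defaultBoostParams <- function(extra = list()) {
  ## exact greedy splits: midpoint cuts between observed values, which
  ## matters for clean margins at these (small) problem sizes
  base <- list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
               subsample = 1, nthread = 1, tree_method = "exact")
  base[names(extra)] <- extra
  base
}

.fitBooster <- function(X, y01, params, nrounds, seed = 0L) {
  d <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
  xgboost::xgb.train(params = c(params, list(seed = as.integer(seed))),
                     data = d, nrounds = nrounds, verbose = 0)
}

.predictBooster <- function(model, X)
  predict(model, xgboost::xgb.DMatrix(X, nthread = 1))

#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test partitions with
#' per-stratum proportions within one sample of the target fraction. The
#' split is reproducible from the seed and, once made, is meant to be reused
#' for every downstream analysis to avoid leakage.
#'
#' @param sampleData Data frame with one row per sample.
#' @param stratifyOn Character vector of column names whose interaction
#'   defines the strata (e.g. endpoint and maneuver).
#' @param trainFraction Target training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
splitData <- function(sampleData, stratifyOn, trainFraction = 0.7, seed = 1L) {
  stopifnot(all(stratifyOn %in% names(sampleData)))
  strata <- interaction(sampleData[stratifyOn], drop = TRUE)
  sizes <- table(strata)
  if (any(sizes < 2L))
    stop("split error: stratum '", names(sizes)[which(sizes < 2L)[1]],
         "' has fewer than 2 members")
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    nTrain <- round(trainFraction * length(idx))
    nTrain <- min(max(nTrain, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, nTrain))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(sampleData)), train))
}

#' Resampling median feature importance
#'
#' Draws `frac` of the training samples without replacement `nIter` times;
#' each iteration z-scores the subsample's features (reproducibility
#' bookkeeping; tree ensembles are scale-insensitive), fits a gradient
#' boosted classifier, and extracts per-feature importances. Subsamples
#' containing a single class are redrawn. Returns the per-feature median
#' importance across iterations (features never used score 0).
#'
#' @param X Feature matrix (samples x features) or a
#'   [BreathFeatureSet-class]; must already be filtered with
#'   [filterModelFeatures()] when it comes from the alignment stage.
#' @param y Two-level factor (or coercible) of sample labels.
#' @param nIter Number of resampling iterations (default 1000).
#' @param frac Subsample fraction (default 2/3).
#' @param learnerParams Named list overriding the booster defaults
#'   (`max_depth` 3, `eta` 0.3).
#' @param nrounds Boosting rounds per iteration (default 30).
#' @param importanceType `"gain"` (default), `"weight"` or `"cover"`.
#' @param seed Integer seed; fully determines the result.
#' @return Named numeric vector of median importances, one per feature.
#' @export
resampleImportance <- function(X, y, nIter = 1000L, frac = 2 / 3,
                               learnerParams = list(), nrounds = 30L,
                               importanceType = c("gain", "weight", "cover"),
                               seed = 1L) {
  if (nIter < 1L) stop("config error: n_iter must be at least 1")
  importanceType <- match.arg(importanceType)
  impCol <- c(gain = "Gain", weight = "Frequency", cover = "Cover")[
    importanceType]
  X <- .asFeatureMatrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("feat%03d", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L)
    stop("resampleImportance() requires exactly two classes")
  y01 <- as.integer(y) - 1L
  params <- .defaultBoostParams(learnerParams)
  n <- nrow(X)
  m <- max(2L, round(frac * n))
  set.seed(seed)
  imp <- matrix(0, nrow = nIter, ncol = ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (i in seq_len(nIter)) {
    repeat {
      idx <- sample(n, m)
      if (length(unique(y01[idx])) == 2L) break
    }
    Xi <- scale(X[idx, , drop = FALSE])
    Xi[!is.finite(Xi)] <- 0  # constant columns within the subsample
    fit <- .fitBooster(Xi, y01[idx], params, nrounds, seed = i)
    tab <- xgboost::xgb.importance(model = fit)
    if (nrow(tab)) imp[i, tab$Feature] <- tab[[impCol]]
  }
  apply(imp, 2, median)
}

#' Consensus feature selection across maneuvers
#'
#' Ranks each maneuver's features by median importance (ties broken toward
#' the lower m/z), truncates each ranking at `topK`, and retains the
#' intersection. Alternatively, `topPercent` selects the top fraction of
#' features per maneuver instead of a fixed count.
#'
#' @param importances Named list of per-maneuver median importance vectors
#'   over the same feature set (e.g. `list(forced = ..., tidal = ...)`).
#' @param topK Ranked-list truncation depth (default 30).
#' @param topPercent If non-`NULL`, use `ceiling(topPercent * nFeatures)`
#'   as the truncation depth instead of `topK` (the "top 10 %" rule is
#'   `topPercent = 0.1`).
#' @return A [SelectionResult-class]; an empty intersection yields a warning
#'   and an empty consensus set.
#' @export
consensusFeatureSelection <- function(importances, topK = 30L,
                                      topPercent = NULL) {
  stopifnot(is.list(importances), length(importances) >= 2L)
  feats <- names(importances[[1]])
  for (imp in importances)
    if (!identical(sort(names(imp)), sort(feats)))
      stop("all importance vectors must cover the same feature set")
  if (!is.null(topPercent))
    topK <- ceiling(topPercent * length(feats))
  topK <- as.integer(topK)

  mzOf <- suppressWarnings(as.numeric(feats))
  ranked <- lapply(importances, function(imp) {
    imp <- imp[feats]
    ord <- order(-imp, mzOf, feats)
    names(imp)[ord][seq_len(min(topK, length(imp)))]
  })
  consensus <- Reduce(intersect, ranked)
  if (!length(consensus))
    warning("consensus is empty: per-maneuver top-", topK,
            " lists do not overlap")
  new("SelectionResult",
      medianImportance = importances,
      rankedLists = ranked, topK = topK,
      consensusFeatures = as.character(consensus),
      nIterations = NA_integer_, subsampleFraction = NA_real_,
      seeds = NA_integer_)
}

#' Run the full resampling-consensus selection for two maneuvers
#'
#' Convenience wrapper: [resampleImportance()] per maneuver on the training
#' samples, then [consensusFeatureSelection()].
#'
#' @param featureSets Named list of two [BreathFeatureSet-class] objects (or
#'   matrices) sharing the feature set, e.g. `list(forced=, tidal=)`.
#' @param y Labels, either one vector shared by both sets or a named list
#'   parallel to `featureSets`.
#' @param topK,topPercent Passed to [consensusFeatureSelection()].
#' @param nIter,frac,learnerParams,nrounds,importanceType,seed Passed to
#'   [resampleImportance()]; each maneuver uses `seed + (position - 1)`.
#' @return A [SelectionResult-class] with the resampling bookkeeping filled
#'   in.
#' @export
selectConsensusFeatures <- function(featureSets, y, topK = 30L,
                                    topPercent = NULL, nIter = 1000L,
                                    frac = 2 / 3, learnerParams = list(),
                                    nrounds = 30L, importanceType = "gain",
                                    seed = 1L) {
  stopifnot(length(featureSets) >= 2L)
  if (!is.list(y)) y <- setNames(rep(list(y), length(featureSets)),
                                 names(featureSets))
  seeds <- seed + seq_along(featureSets) - 1L
  imps <- mapply(function(fs, yy, s)
    resampleImportance(fs, yy, nIter = nIter, frac = frac,
                       learnerParams = learnerParams, nrounds = nrounds,
                       importanceType = importanceType, seed = s),
    featureSets, y[names(featureSets)], seeds, SIMPLIFY = FALSE)
  sel <- consensusFeatureSelection(imps, topK = topK,
                                   topPercent = topPercent)
  sel@nIterations <- as.integer(nIter)
  sel@subsampleFraction <- frac
  sel@seeds <- as.integer(seeds)
  sel
}

.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.aucOf <- function(y01, prob) {
  as.numeric(pROC::auc(pROC::roc(response = y01, predictor = prob,
                                 quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Tune and fit the gradient-boosted classifier
#'
#' Grid search by mean AUC over stratified k-fold cross-validation on the
#' training set, then a final refit on the full training set with the best
#' configuration (ties resolved toward the first grid row).
#'
#' @param X Training feature matrix or [BreathFeatureSet-class].
#' @param y Two-level labels.
#' @param cvFolds Number of stratified folds (default 5).
#' @param paramGrid Data frame of candidate configurations with columns
#'   among `max_depth`, `eta`, `subsample`, `nrounds`. The default is a
#'   small grid: depth 2/4, eta 0.1/0.3, 50 rounds.
#' @param seed Integer seed (fold assignment and booster seeding).
#' @return List with `model` (an `xgb.Booster`), `bestParams`, `cvAUC`
#'   (mean CV AUC of the best configuration), `features` (column names) and
#'   `positiveClass` (second factor level).
#' @export
tuneAndFit <- function(X, y, cvFolds = 5L,
                       paramGrid = expand.grid(max_depth = c(2, 4),
                                               eta = c(0.1, 0.3),
                                               nrounds = 50),
                       seed = 1L) {
  X <- .asFeatureMatrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("tuneAndFit() requires exactly two classes")
  y01 <- as.integer(y) - 1L
  if (min(table(y)) < cvFolds)
    cvFolds <- max(2L, min(table(y)))
  fold <- .stratifiedFolds(y, cvFolds, seed)
  cvAUC <- numeric(nrow(paramGrid))
  for (p in seq_len(nrow(paramGrid))) {
    cfg <- as.list(paramGrid[p, setdiff(names(paramGrid), "nrounds"),
                             drop = FALSE])
    nrounds <- paramGrid$nrounds[p] %||% 50
    aucs <- numeric(cvFolds)
    for (f in seq_len(cvFolds)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y01[te])) < 2L || length(unique(y01[tr])) < 2L)
        stop("CV error: a fold lost one of the classes")
      fit <- .fitBooster(X[tr, , drop = FALSE], y01[tr],
                         .defaultBoostParams(cfg), nrounds, seed = seed + f)
      aucs[f] <- .aucOf(y01[te], .predictBooster(fit, X[te, , drop = FALSE]))
    }
    cvAUC[p] <- mean(aucs)
  }
  best <- which.max(cvAUC)
  cfg <- as.list(paramGrid[best, setdiff(names(paramGrid), "nrounds"),
                           drop = FALSE])
  nrounds <- paramGrid$nrounds[best] %||% 50
  model <- .fitBooster(X, y01, .defaultBoostParams(cfg), nrounds,
                       seed = seed)
  list(model = model, bestParams = c(cfg, list(nrounds = nrounds)),
       cvAUC = cvAUC[best], features = colnames(X),
       positiveClass = levels(y)[2])
}

.thresholdMetrics <- function(y01, prob, threshold) {
  pos <- prob >= threshold
  tp <- sum(pos & y01 == 1); fn <- sum(!pos & y01 == 1)
  tn <- sum(!pos & y01 == 0); fp <- sum(pos & y01 == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

#' Evaluate a classifier at a probability threshold
#'
#' Hold-out evaluation predicts the supplied samples with the fitted model;
#' leave-one-out (LOO) evaluation refits the model (fixed best
#' hyperparameters) once per left-out sample and aggregates the
#' out-of-sample probabilities before computing the AUC and the confusion
#' metrics. Probabilities at or above the threshold are called positive.
#'
#' @param fit Result of [tuneAndFit()].
#' @param X Evaluation matrix: the held-out test set (`scheme = "holdout"`)
#'   or the full modeling set (`scheme = "loo"`).
#' @param y Labels for `X`.
#' @param threshold Probability threshold (default 0.5).
#' @param scheme `"holdout"` (default) or `"loo"`.
#' @param endpoint Label stored in the report (default `"diagnosis"`).
#' @param nTrain Training-set size recorded in the report (defaults to
#'   `nrow(X)` for LOO).
#' @return A [ModelReport-class].
#' @export
evaluateModel <- function(fit, X, y, threshold = 0.5,
                          scheme = c("holdout", "loo"),
                          endpoint = "diagnosis", nTrain = NULL) {
  scheme <- match.arg(scheme)
  X <- .asFeatureMatrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("AUC undefined: evaluation labels contain a single class")
  y01 <- as.integer(y) - 1L
  if (scheme == "holdout") {
    prob <- .predictBooster(fit$model, X)
    nTr <- nTrain %||% NA_integer_
    nTe <- nrow(X)
  } else {
    params <- .defaultBoostParams(
      fit$bestParams[setdiff(names(fit$bestParams), "nrounds")])
    nrounds <- fit$bestParams$nrounds %||% 50
    prob <- vapply(seq_len(nrow(X)), function(i) {
      m <- .fitBooster(X[-i, , drop = FALSE], y01[-i], params, nrounds,
                       seed = i)
      .predictBooster(m, X[i, , drop = FALSE])
    }, numeric(1))
    nTr <- nrow(X) - 1L
    nTe <- nrow(X)
  }
  met <- .thresholdMetrics(y01, prob, threshold)
  new("ModelReport", endpoint = endpoint, auc = .aucOf(y01, prob),
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv, threshold = threshold,
      cvScheme = if (scheme == "holdout") "holdout" else "loo",
      nTrain = as.integer(nTr %||% NA_integer_), nTest = as.integer(nTe))
}
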