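## End-to-end orchestration: preprocess -> features -> selection -> models,
## with a JSON manifest of every artifact for reproducibility audits.

#' Assemble a pipeline configuration
#'
#' Collects the stage parameters, seeds and I/O locations for
#' [runPipeline()]. Every stochastic stage derives its seed from `seed`.
#'
#' @param recordings Named list of [RawRecording-class] objects or recording
#'   bundle paths; names are sample identifiers. Each recording's metadata
#'   must carry `subject_id` and `maneuver`.
#' @param cohort Data frame of clinical covariates with a `subject_id`
#'   column (see [simulateCohort()] for the layout).
#' @param outputDir Directory for artifacts (created if needed).
#' @param endpointColumn Cohort column holding the diagnosis endpoint
#'   (default `"group"`).
#' @param diagnosisContrast Two endpoint levels to model, positive class
#'   second (default `c("control", "asthma")`).
#' @param waterAdductMz,tracerMzs,eicWindow,waterThreshold Breath-phase
#'   segmentation settings (defaults m/z 37.038; 69.07/63.02/55.03;
#'   0.05 Da; 2e5 cps).
#' @param referenceMzs,capnostatMax,calibrantPpmMax,minCycles QC settings.
#' @param sgWindow,sgOrder,minProminenceRel,minIntensityCps Composite
#'   spectrum and peak detection settings.
#' @param internalStandardMz,minMz Normalization and model-filter settings.
#' @param trainFraction,nIter,frac,topK,cvFolds Modeling settings (defaults
#'   0.7, 1000, 2/3, 30, 5).
#' @param threshold Probability threshold for reported metrics (default 0.5).
#' @param seed Master integer seed.
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(recordings, cohort, outputDir,
                           endpointColumn = "group",
                           diagnosisContrast = c("control", "asthma"),
                           waterAdductMz = 37.038,
                           tracerMzs = c(69.07, 63.02, 55.03),
                           eicWindow = 0.05, waterThreshold = 2e5,
                           referenceMzs = c(21.0220, 203.94299, 330.85),
                           capnostatMax = 3.5, calibrantPpmMax = 100,
                           minCycles = 3L, sgWindow = 7L, sgOrder = 3L,
                           minProminenceRel = 0.5, minIntensityCps = 100,
                           internalStandardMz = 22.0274, minMz = 42,
                           trainFraction = 0.7, nIter = 1000L, frac = 2 / 3,
                           topK = 30L, cvFolds = 5L, threshold = 0.5,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.loadRecording <- function(x) {
  if (is(x, "RawRecording")) x else readRecording(x)
}

#' Run the full diagnosis pipeline
#'
#' For every recording: recalibration, EIC extraction, breath-phase
#' segmentation and QC. Composite spectra of the QC-passing samples are
#' peak-picked, aligned into a feature matrix, normalized to the internal
#' standard and filtered for modeling. One stratified 70/30 split (endpoint
#' x maneuver) is drawn once; per-maneuver resampling importances on the
#' training samples feed the top-k consensus, and one classifier per
#' maneuver is tuned, refitted and evaluated on its held-out samples.
#' Artifacts (QC report, feature matrix, selection, model reports) are
#' written to the output directory together with a manifest carrying their
#' MD5 checksums; identical configurations and seeds reproduce identical
#' manifests.
#'
#' @param cfg A `"PipelineConfig"` from [pipelineConfig()].
#' @return The manifest, invisibly a list (also written as
#'   `manifest.json`): QC summary, artifact paths and checksums, consensus
#'   feature list, and one [ModelReport-class] per maneuver (as data frame
#'   rows in the JSON).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cfg$recordings)
  if (is.null(ids)) stop("recordings must be a named list")

  ## --- stage 1: per-recording preprocessing + QC -------------------------
  qcRows <- list(); peaklists <- list(); sampleMeta <- list()
  for (id in ids) {
    res <- tryCatch({
      rec <- .loadRecording(cfg$recordings[[id]])
      cal <- recalibrate(rec, cfg$referenceMzs)
      rec <- cal$recording
      water <- extractEIC(rec, cfg$waterAdductMz, cfg$eicWindow)
      tracers <- lapply(cfg$tracerMzs, extractEIC, rec = rec,
                        window = cfg$eicWindow)
      phase <- segmentBreaths(water, tracers, cfg$waterThreshold)
      qc <- qcRecording(rec, phase, cal$model,
                        capnostatMax = cfg$capnostatMax,
                        calibrantPpmMax = cfg$calibrantPpmMax,
                        minCycles = cfg$minCycles)
      list(rec = rec, phase = phase, qc = qc)
    }, error = function(e)
      stop("stage preprocess failed for sample '", id, "': ",
           conditionMessage(e)))
    qcRows[[id]] <- data.frame(
      sample = id, overall_pass = res$qc@overallPass,
      capnostat_pass = res$qc@capnostatPass,
      calibrant_pass = res$qc@calibrantPass,
      cycles_pass = res$qc@cyclesPass,
      cycle_count = res$qc@details$cycle_count,
      n_selected = length(res$phase@selected))
    if (res$qc@overallPass && length(res$phase@selected)) {
      comp <- compositeSpectrum(res$rec, res$phase@selected,
                                cfg$sgWindow, cfg$sgOrder)
      peaklists[[id]] <- detectPeaks(comp, cfg$minProminenceRel,
                                     cfg$minIntensityCps)
      md <- res$rec@metadata
      sampleMeta[[id]] <- data.frame(
        sample = id, subject_id = md$subject_id %||% id,
        maneuver = md$maneuver %||% "tidal")
    }
  }
  qcTable <- do.call(rbind, qcRows)
  if (length(peaklists) == 0L) stop("no samples passed QC")

  ## --- stage 2: feature matrix -------------------------------------------
  meta <- do.call(rbind, sampleMeta)
  rownames(meta) <- meta$sample
  meta <- merge(meta, cfg$cohort, by = "subject_id", sort = FALSE)
  rownames(meta) <- meta$sample
  meta <- meta[names(peaklists), , drop = FALSE]
  fm <- alignFeatures(peaklists, sampleData = meta)
  fm <- normalizeFeatures(fm, cfg$internalStandardMz)
  fmModel <- filterModelFeatures(fm, cfg$referenceMzs, cfg$minMz)

  ## --- stage 3: selection + per-maneuver models --------------------------
  cd <- as.data.frame(SummarizedExperiment::colData(fmModel))
  endpoint <- cd[[cfg$endpointColumn]]
  inModel <- endpoint %in% cfg$diagnosisContrast
  modelSet <- fmModel[, inModel]
  cdM <- cd[inModel, , drop = FALSE]
  y <- factor(cdM[[cfg$endpointColumn]], levels = cfg$diagnosisContrast)
  split <- splitData(cdM, c(cfg$endpointColumn, "maneuver"),
                     cfg$trainFraction, seed = cfg$seed)
  maneuvers <- sort(unique(cdM$maneuver))

  trainSets <- lapply(maneuvers, function(mv) {
    idx <- intersect(split$train, which(cdM$maneuver == mv))
    list(X = modelSet[, idx], y = y[idx], idx = idx)
  })
  names(trainSets) <- maneuvers
  sel <- selectConsensusFeatures(
    lapply(trainSets, `[[`, "X"), lapply(trainSets, `[[`, "y"),
    topK = cfg$topK, nIter = cfg$nIter, frac = cfg$frac,
    seed = cfg$seed + 100L)
  if (!length(sel@consensusFeatures))
    stop("no consensus features selected; cannot fit models")

  keepFeat <- match(sel@consensusFeatures,
                    sprintf("%.4f", featureMz(modelSet)))
  reports <- list()
  for (mv in maneuvers) {
    trIdx <- trainSets[[mv]]$idx
    teIdx <- intersect(split$test, which(cdM$maneuver == mv))
    Xtr <- .asFeatureMatrix(modelSet[keepFeat, trIdx])
    Xte <- .asFeatureMatrix(modelSet[keepFeat, teIdx])
    fit <- tuneAndFit(Xtr, y[trIdx], cvFolds = cfg$cvFolds,
                      seed = cfg$seed + 200L)
    reports[[mv]] <- evaluateModel(fit, Xte, y[teIdx],
                                   threshold = cfg$threshold,
                                   scheme = "holdout",
                                   endpoint = "diagnosis",
                                   nTrain = length(trIdx))
  }

  ## --- stage 4: artifacts + manifest -------------------------------------
  paths <- c(qc = file.path(cfg$outputDir, "qc.json"),
             features = file.path(cfg$outputDir, "feature_matrix.csv"),
             selection = file.path(cfg$outputDir, "selection.json"),
             reports = file.path(cfg$outputDir, "model_reports.json"))
  jsonlite::write_json(qcTable, paths[["qc"]], auto_unbox = TRUE,
                       digits = NA)
  writeFeatureMatrix(fm, paths[["features"]])
  jsonlite::write_json(
    list(consensus = sel@consensusFeatures, ranked = sel@rankedLists,
         top_k = sel@topK, n_iterations = sel@nIterations,
         subsample_fraction = sel@subsampleFraction),
    paths[["selection"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(reports, as.data.frame), paths[["reports"]],
    auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    qc_summary = list(n_recordings = length(ids),
                      n_passed = sum(qcTable$overall_pass)),
    artifacts = lapply(as.list(paths), function(p)
      list(path = basename(p),
           md5 = unname(tools::md5sum(p)))),
    n_features = nrow(fm), n_model_features = nrow(fmModel),
    consensus_features = sel@consensusFeatures,
    model_reports = lapply(reports, as.data.frame),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(manifest, list(featureSet = fm, selection = sel,
                             reports = reports, qc = qcTable)))
}

#' Run the bronchodilator-responsiveness pipeline
#'
#' Restricts the cohort to asthma and COPD subjects (controls never enter
#' BDR modeling), selects consensus VOC features across the two maneuvers on
#' the BDR label, concatenates them with the clinical covariates (FeNO,
#' blood eosinophils, total IgE, pre-bronchodilator FEV1 %predicted), tunes
#' a gradient-boosted classifier and evaluates it with leave-one-out
#' cross-validation at the probability threshold.
#'
#' @param cohort Cohort data frame with a `bdr` column (`"positive"` /
#'   `"negative"`; computed with [labelBDR()] when absent and the spirometry
#'   deltas are present).
#' @param featureSets Named list of two [BreathFeatureSet-class] objects
#'   (`tidal`, `forced`) whose `colData` links samples to `subject_id`;
#'   already normalized and model-filtered.
#' @param maneuver Which maneuver's matrix feeds the final LOO model
#'   (default `"forced"`).
#' @param covariates Clinical covariate columns to include (default FeNO,
#'   eosinophils, IgE, FEV1 %predicted).
#' @param nIter,frac,topK Selection settings (defaults 1000, 2/3, 30).
#' @param cvFolds,threshold Tuning folds and reporting threshold.
#' @param seed Integer seed.
#' @return List with `report` ([ModelReport-class], LOO) and `selection`
#'   ([SelectionResult-class]).
#' @export
runBDRPipeline <- function(cohort, featureSets, maneuver = "forced",
                           covariates = c("feno_ppb", "eos_10e9_l",
                                          "ige_iu_ml", "fev1_pct_pred"),
                           nIter = 1000L, frac = 2 / 3, topK = 30L,
                           cvFolds = 5L, threshold = 0.5, seed = 1L) {
  if (!"bdr" %in% names(cohort)) {
    if (!all(c("delta_fev1_pct_pred", "delta_fvc_pct_pred") %in%
             names(cohort)))
      stop("cohort lacks a 'bdr' column and the spirometry deltas")
    cohort$bdr <- NA_character_
    hasDelta <- !(is.na(cohort$delta_fev1_pct_pred) &
                    is.na(cohort$delta_fvc_pct_pred))
    cohort$bdr[hasDelta] <- labelBDR(cohort$delta_fev1_pct_pred[hasDelta],
                                     cohort$delta_fvc_pct_pred[hasDelta])
  }
  keep <- cohort$group %in% c("asthma", "copd") & !is.na(cohort$bdr)
  if (!any(keep)) stop("no asthma/COPD subjects with BDR labels")
  cohort <- cohort[keep, , drop = FALSE]

  subsetSet <- function(fs) {
    cd <- as.data.frame(SummarizedExperiment::colData(fs))
    idx <- which(cd$subject_id %in% cohort$subject_id)
    fs[, idx]
  }
  featureSets <- lapply(featureSets, subsetSet)
  yOf <- function(fs) {
    cd <- as.data.frame(SummarizedExperiment::colData(fs))
    factor(cohort$bdr[match(cd$subject_id, cohort$subject_id)],
           levels = c("negative", "positive"))
  }
  ys <- lapply(featureSets, yOf)

  sel <- selectConsensusFeatures(featureSets, ys, topK = topK,
                                 nIter = nIter, frac = frac, seed = seed)
  fs <- featureSets[[maneuver]]
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  Xvoc <- .asFeatureMatrix(fs)[, sel@consensusFeatures, drop = FALSE]
  covariates <- intersect(covariates, names(cohort))
  Xclin <- as.matrix(
    cohort[match(cd$subject_id, cohort$subject_id), covariates,
           drop = FALSE])
  X <- cbind(Xvoc, Xclin)
  y <- ys[[maneuver]]

  fit <- tuneAndFit(X, y, cvFolds = cvFolds, seed = seed + 1L)
  report <- evaluateModel(fit, X, y, threshold = threshold, scheme = "loo",
                          endpoint = "bdr")
  list(report = report, selection = sel)
}
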