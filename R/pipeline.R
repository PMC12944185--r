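#' Pipeline run configuration
#'
#' Bundles every stage's settings with defaults matching the method's
#' canonical analysis: 1 mm^3 resampling, fixed-bin-width discretization
#' (width 5 for raw MR signal; narrower widths for the parametric maps,
#' whose value ranges are far below 5 — see [extractionConfig()]), variance
#' threshold 0.01, correlation threshold 0.8, 10-fold CV LASSO, 8:2
#' stratified split, square-root-balanced one-vs-all boosting, isotonic
#' calibration, decision-level fusion, and 1000-replicate bootstrap CIs.
#'
#' @param phantom a [phantomSpec()] describing the synthetic cohort.
#' @param binWidths named list of per-source discretization bin widths.
#' @param varThreshold,rMax,folds selection settings.
#' @param splitRatio training fraction of the stratified split.
#' @param boost [boostParams()].
#' @param bootstrapReps bootstrap replicates for CIs.
#' @param seed master seed; stage seeds are derived deterministically.
#' @export
runConfig <- function(phantom = phantomSpec(),
                      binWidths = list(TICWIR = 0.001, TICArea = 0.05,
                                       MRORI = 5),
                      varThreshold = 0.01, rMax = 0.8, folds = 10L,
                      splitRatio = 0.8, boost = boostParams(),
                      bootstrapReps = 1000L, seed = 1L) {
  structure(list(phantom = phantom, binWidths = binWidths,
                 varThreshold = varThreshold, rMax = rMax, folds = folds,
                 splitRatio = splitRatio, boost = boost,
                 bootstrapReps = as.integer(bootstrapReps),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Compute the three per-patient source images
#'
#' @param series a [DCESeries-class]; @param mask its [TumorMask-class].
#' @return list with `TICWIR`, `TICArea` (3D arrays, the parametric maps)
#'   and `MRORI` (the peak-enhancement phase volume).
#' @export
sourceImages <- function(series, mask) {
  list(TICWIR = mapArray(computeWIRMap(series)),
       TICArea = mapArray(computeAreaMap(series)),
       MRORI = peakEnhancementPhase(series, mask)$volume)
}

#' Extract feature tables for a cohort
#'
#' @param cohort output of [generateCohort()] (or a compatible list of
#'   records with `series`, `mask`).
#' @param config a [runConfig()].
#' @return named list of three feature data.frames (`TICWIR`, `TICArea`,
#'   `MRORI`), rows aligned with `cohort$labels`.
#' @export
cohortFeatureTables <- function(cohort, config = runConfig()) {
  sources <- names(config$binWidths)
  lists <- stats::setNames(lapply(sources, function(s) list()), sources)
  for (pid in cohort$labels$patient_id) {
    rec <- cohort$patients[[pid]]
    imgs <- sourceImages(rec$series, rec$mask)
    for (s in sources) {
      cfg <- extractionConfig(binWidth = config$binWidths[[s]])
      lists[[s]][[pid]] <- extractFeatures(imgs[[s]], maskArray(rec$mask),
                                           voxelSpacing(rec$series), cfg)
    }
  }
  stats::setNames(lapply(sources, function(s) featureTable(lists[[s]], s)),
                  sources)
}

# out-of-fold raw one-vs-all probabilities on the training split, with the
# whole per-source pipeline (three-step selection + boosted model) refit on
# each calibration-fold complement so no row's prediction has seen its label
.nestedTrainRaw <- function(trainTab, yTrain, config, sourceType,
                            folds = 5L, seed = 1L) {
  y <- factor(yTrain, levels = subtypeLevels())
  set.seed(seed)
  foldid <- integer(nrow(trainTab))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  raw <- matrix(NA_real_, nrow(trainTab), 3,
                dimnames = list(rownames(trainTab), subtypeLevels()))
  for (k in seq_len(folds)) {
    inFold <- foldid == k
    selF <- selectFeatures(trainTab[!inFold, , drop = FALSE], yTrain[!inFold],
                           config$varThreshold, config$rMax,
                           folds = max(3L, min(config$folds,
                                               min(table(y[!inFold])))),
                           seed = seed + 100L + k)
    mF <- trainBase(applySelection(selF, trainTab[!inFold, , drop = FALSE]),
                    yTrain[!inFold], sourceType = sourceType,
                    params = config$boost, seed = seed + 200L + k)
    raw[inFold, ] <- predictProb(
      mF, applySelection(selF, trainTab[inFold, , drop = FALSE]),
      normalize = FALSE)
  }
  raw
}

#' Run the full phantom-to-report pipeline
#'
#' Generates (or accepts) a synthetic cohort, computes the TIC-WIR and
#' TIC-Area parametric maps and the peak-enhancement baseline image,
#' extracts the 851-feature panel from each, performs the three-step
#' selection per source on the training split, trains the three base models
#' and the calibrated decision-level fusion model, and evaluates everything
#' on the held-out validation split.
#'
#' @param config a [runConfig()].
#' @param runDir optional output directory for artifacts (selection JSON,
#'   metrics JSON, label table).
#' @param cohort optional pre-generated cohort (otherwise generated from
#'   `config$phantom`).
#' @return a `PipelineResult` list: `labels`, `split`, `selection` (per
#'   source), `models`, `calibrators`, `valProbs` (per model), `reports`
#'   (per model [evaluateModel()] output), `delong` (fusion vs each other
#'   model), `fusionAttribution`.
#' @export
runPipeline <- function(config = runConfig(), runDir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  log <- function(...) message(sprintf("[%.1fs] ", as.numeric(Sys.time() - t0)), ...)

  if (is.null(cohort)) {
    log("generating phantom cohort (", sum(config$phantom$nPerClass), " patients)")
    cohort <- generateCohort(config$phantom)
  }
  labels <- cohort$labels
  log("computing parametric maps and extracting features")
  tables <- cohortFeatureTables(cohort, config)

  split <- splitCohort(labels, config$splitRatio, config$seed)
  yTrain <- labels$subtype[split$train]
  yVal <- labels$subtype[split$validation]

  selection <- list(); models <- list(); calibrators <- list()
  trainCal <- list(); valCal <- list(); valProbs <- list()
  for (s in names(tables)) {
    log("selecting features and training model: ", s)
    tab <- tables[[s]]
    trainTab <- tab[split$train, , drop = FALSE]
    sel <- selectFeatures(trainTab, yTrain,
                          config$varThreshold, config$rMax, config$folds,
                          seed = config$seed + 11L)
    selection[[s]] <- sel
    trainX <- applySelection(sel, trainTab)
    valX <- applySelection(sel, tab[split$validation, , drop = FALSE])
    mdl <- trainBase(trainX, yTrain, sourceType = s, params = config$boost,
                     seed = config$seed + 23L)
    models[[s]] <- mdl
    # out-of-fold training probabilities with selection redone per fold:
    # leak-free inputs for the calibrators and the fusion stacking stage
    oofRaw <- .nestedTrainRaw(trainTab, yTrain, config, sourceType = s,
                              seed = config$seed + 29L)
    calibrators[[s]] <- fitCalibratorsRaw(oofRaw, yTrain)
    trainCal[[s]] <- applyCalibrators(calibrators[[s]], oofRaw)
    valCal[[s]] <- applyCalibrators(calibrators[[s]],
                                    predictProb(mdl, valX, normalize = FALSE))
    valProbs[[s]] <- predictProb(mdl, valX)
  }

  log("training fusion model")
  fusionBoost <- config$boost
  fusionBoost$maxDepth <- min(fusionBoost$maxDepth, 3L)  # 6-column meta-input
  fusion <- trainFusion(trainCal$TICWIR, trainCal$TICArea, yTrain,
                        params = fusionBoost, seed = config$seed + 31L)
  models$fusion <- fusion
  fusValX <- fusionInputs(valCal$TICWIR, valCal$TICArea)
  valProbs$fusion <- predictProb(fusion, fusValX)

  log("evaluating on the held-out split (n = ", length(yVal), ")")
  reports <- list()
  for (s in names(valProbs))
    reports[[s]] <- evaluateModel(valProbs[[s]], yVal, config$bootstrapReps,
                                  seed = config$seed + 41L)
  delong <- list()
  for (s in c("TICWIR", "TICArea", "MRORI"))
    delong[[s]] <- compareModelsMicro(valProbs$fusion, valProbs[[s]], yVal)
  fusionAttr <- attributionSummary(fusion, fusValX)

  result <- structure(list(
    labels = labels, split = split, selection = selection, models = models,
    calibrators = calibrators, valProbs = valProbs, reports = reports,
    delong = delong, fusionAttribution = fusionAttr, config = config
  ), class = "PipelineResult")

  if (!is.null(runDir)) {
    if (!dir.exists(runDir)) dir.create(runDir, recursive = TRUE)
    utils::write.csv(labels, file.path(runDir, "labels.csv"), row.names = FALSE)
    for (s in names(selection))
      writeSelection(selection[[s]], file.path(runDir, paste0("selection_", s, ".json")))
    metrics <- lapply(reports, function(r)
      list(micro = r$microAUC, macro = r$macroAUC, ovr = r$ovrAUC,
           metrics = r$metrics))
    metrics$delong_p <- lapply(delong, function(d) d$p)
    jsonlite::write_json(metrics, file.path(runDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    log("artifacts written to ", runDir)
  }
  invisible(result)
}
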