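#' @include AllClasses.R AllGenerics.R model.R metrics.R dataset.R
NULL

#' Aggregate annual disturbed area from examples and predictions
#'
#' For each target year present in the examples: observed area = number of
#' positive labels times the cell area, predicted area = number of
#' positive binary predictions times the cell area (0.09 ha per cell at
#' the 30 m grain). The observed series depends on labels only, so it is
#' identical whichever model produced the predictions.
#'
#' @param examples a [BeetleExampleSet].
#' @param binaryPredictions 0/1 vector aligned with the examples.
#' @param cellAreaHa area of one cell in hectares (0.09 at 30 m).
#' @return data.frame with columns `year`, `observedHa`, `predictedHa`.
#' @export
annualDisturbedArea <- function(examples, binaryPredictions,
                                cellAreaHa = 0.09) {
  stopifnot(length(binaryPredictions) == ncol(examples))
  yrs <- sort(unique(examples$year))
  obs <- vapply(yrs, function(y)
    sum(examples$label[examples$year == y]) * cellAreaHa, 0)
  pred <- vapply(yrs, function(y)
    sum(binaryPredictions[examples$year == y]) * cellAreaHa, 0)
  data.frame(year = yrs, observedHa = obs, predictedHa = pred)
}

## Assemble per-year probability maps: NA where no example was scored.
.probMaps <- function(examples, probs, gridDim) {
  yrs <- sort(unique(examples$year))
  maps <- lapply(yrs, function(y) {
    m <- matrix(NA_real_, gridDim[1], gridDim[2])
    sel <- examples$year == y
    m[cbind(examples$row[sel], examples$col[sel])] <- probs[sel]
    m
  })
  names(maps) <- yrs
  maps
}

.runExperiment <- function(landscape, modelConfig, split, splitDesc, seed,
                           withGleich) {
  trainSet <- split$train; testSet <- split$test
  fit <- trainClassifier(buildClassifier(modelConfig), trainSet, testSet)
  pTrain <- predictProba(fit, trainSet)
  th <- selectThreshold(pTrain, trainSet$label)
  fit <- setThreshold(fit, th)
  pTest <- predictProba(fit, testSet)
  pred <- as.integer(pTest >= th)
  report <- metricReport(confusionCounts(testSet$label, pred))
  yrs <- sort(unique(testSet$year))
  perYear <- lapply(yrs, function(y) {
    sel <- testSet$year == y
    metricReport(confusionCounts(testSet$label[sel], pred[sel]))
  })
  names(perYear) <- yrs
  cellAreaHa <- (landscape@cellSize / 100)^2
  annual <- annualDisturbedArea(testSet, pred, cellAreaHa)
  gl <- if (withGleich && nrow(annual) >= 2L)
    gleichlaeufigkeit(annual$observedHa, annual$predictedHa) else NA_real_
  maps <- .probMaps(testSet, pTest, dim(landscape@host))
  methods::new("ExperimentResult", report = report, threshold = th,
               perYearReports = perYear, annualSeries = annual,
               probabilityMaps = maps, gleichlaeufigkeit = gl,
               classifier = fit,
               provenance = list(config = modelConfig, seed = seed,
                                 split = splitDesc,
                                 nTrain = ncol(trainSet),
                                 nTest = ncol(testSet)))
}

#' Year-holdout experiment (forward-prediction design)
#'
#' Builds the example set, holds out entire target years (in the study:
#' one year from each outbreak stage), trains on the remaining years with
#' the holdout as evaluation set for best-epoch selection, calibrates the
#' F1-maximizing threshold on training predictions, and evaluates on the
#' held-out years — pooled and per year, with per-year probability maps.
#'
#' @param landscape a [LandscapeSeries].
#' @param modelConfig a [ModelConfig]; its seed is overridden by `seed`.
#' @param holdoutYears integer years to hold out (each needs two
#'   predecessors in the series).
#' @param seed integer seed controlling training.
#' @param hostMortality see [buildExamples()].
#' @return an [ExperimentResult].
#' @export
runExperimentYearHoldout <- function(landscape, modelConfig, holdoutYears,
                                     seed = 1L, hostMortality = TRUE) {
  modelConfig@seed <- as.integer(seed)
  examples <- buildExamples(landscape, hostMortality = hostMortality)
  split <- splitByYears(examples, holdoutYears)
  .runExperiment(landscape, modelConfig, split,
                 list(mode = "years", holdoutYears = holdoutYears), seed,
                 withGleich = FALSE)
}

#' Random-holdout experiment (temporal-dynamics design)
#'
#' Sets aside a random fraction of all examples as test set, trains on the
#' rest, and — besides the pooled metric report — aggregates the observed
#' and predicted annual disturbed area over the test examples and scores
#' their agreement with Gleichlaeufigkeit. This design probes whether the
#' model captures the multi-year outbreak pulse, not forward prediction.
#'
#' @param landscape a [LandscapeSeries].
#' @param modelConfig a [ModelConfig]; its seed is overridden by `seed`.
#' @param fraction test fraction in (0, 1) (0.2 in the study design).
#' @param seed integer seed controlling the split and training.
#' @param hostMortality see [buildExamples()].
#' @return an [ExperimentResult] with `gleichlaeufigkeit` filled in.
#' @export
runExperimentRandom <- function(landscape, modelConfig, fraction = 0.2,
                                seed = 1L, hostMortality = TRUE) {
  modelConfig@seed <- as.integer(seed)
  examples <- buildExamples(landscape, hostMortality = hostMortality)
  split <- splitRandom(examples, fraction, seed = seed)
  .runExperiment(landscape, modelConfig, split,
                 list(mode = "random", fraction = fraction), seed,
                 withGleich = TRUE)
}

#' Permutation null for the annual-series Gleichlaeufigkeit
#'
#' Permutes the binary predictions across examples (breaking their
#' association with years), recomputes the predicted annual series, and
#' returns the null distribution of Gleichlaeufigkeit against the
#' observed series. An adequately trained model should exceed the 95th
#' percentile of this null.
#'
#' @param examples the scored [BeetleExampleSet].
#' @param binaryPredictions 0/1 predictions aligned with `examples`.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param cellAreaHa cell area in hectares.
#' @return numeric vector of `nPerm` null Gleichlaeufigkeit values.
#' @export
gleichlaeufigkeitNull <- function(examples, binaryPredictions, nPerm = 100L,
                                  seed = 1L, cellAreaHa = 0.09) {
  obs <- annualDisturbedArea(examples, binaryPredictions, cellAreaHa)
  set.seed(seed)
  vapply(seq_len(nPerm), function(i) {
    perm <- sample(binaryPredictions)
    a <- annualDisturbedArea(examples, perm, cellAreaHa)
    gleichlaeufigkeit(obs$observedHa, a$predictedHa)
  }, 0)
}
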