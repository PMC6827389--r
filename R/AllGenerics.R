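#' @include AllClasses.R
NULL

#' Accessors for LandscapeSeries
#'
#' @param x a [LandscapeSeries].
#' @return `hostMap`: integer matrix; `attackMaps`: integer array
#'   (rows x cols x years); `temperatureMap`: numeric matrix;
#'   `regionalVolume`: named numeric vector; `landscapeYears`: integer
#'   vector; `cellSize`: numeric scalar (metres).
#' @name LandscapeSeries-accessors
#' @aliases hostMap attackMaps temperatureMap regionalVolume landscapeYears
#'   cellSize
NULL

#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("hostMap", function(x) standardGeneric("hostMap"))
#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("attackMaps", function(x) standardGeneric("attackMaps"))
#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("temperatureMap", function(x) standardGeneric("temperatureMap"))
#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("regionalVolume", function(x) standardGeneric("regionalVolume"))
#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("landscapeYears", function(x) standardGeneric("landscapeYears"))
#' @rdname LandscapeSeries-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname LandscapeSeries-accessors
setMethod("hostMap", "LandscapeSeries", function(x) x@host)
#' @rdname LandscapeSeries-accessors
setMethod("attackMaps", "LandscapeSeries", function(x) x@attacks)
#' @rdname LandscapeSeries-accessors
setMethod("temperatureMap", "LandscapeSeries", function(x) x@temperature)
#' @rdname LandscapeSeries-accessors
setMethod("regionalVolume", "LandscapeSeries", function(x) x@regionalVolume)
#' @rdname LandscapeSeries-accessors
setMethod("landscapeYears", "LandscapeSeries", function(x) x@years)
#' @rdname LandscapeSeries-accessors
setMethod("cellSize", "LandscapeSeries", function(x) x@cellSize)

setMethod("show", "LandscapeSeries", function(object) {
  d <- dim(object@host)
  cat(sprintf("LandscapeSeries: %d x %d cells at %g m, %d years (%d-%d)\n",
              d[1], d[2], object@cellSize, length(object@years),
              min(object@years), max(object@years)))
  cat(sprintf("  host cells: %d (%.1f%%)\n", sum(object@host == 1L, na.rm = TRUE),
              100 * mean(object@host == 1L, na.rm = TRUE)))
  att <- apply(object@attacks, 3, sum)
  cat(sprintf("  attacked cells/yr: min %d, median %g, max %d\n",
              min(att), stats::median(att), max(att)))
  invisible(NULL)
})

#' Accessors for BeetleExampleSet
#'
#' @param x a [BeetleExampleSet].
#' @return `exampleWindows`: the 361 x n integer code matrix;
#'   `exampleLabels`: integer 0/1 vector; `classCounts`: named integer
#'   vector `c(positive=, negative=)`.
#' @name BeetleExampleSet-accessors
#' @aliases exampleWindows exampleLabels classCounts
NULL

#' @rdname BeetleExampleSet-accessors
#' @export
setGeneric("exampleWindows", function(x) standardGeneric("exampleWindows"))
#' @rdname BeetleExampleSet-accessors
#' @export
setGeneric("exampleLabels", function(x) standardGeneric("exampleLabels"))
#' @rdname BeetleExampleSet-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname BeetleExampleSet-accessors
setMethod("exampleWindows", "BeetleExampleSet",
          function(x) SummarizedExperiment::assay(x, "window"))
#' @rdname BeetleExampleSet-accessors
setMethod("exampleLabels", "BeetleExampleSet", function(x) x$label)
#' @rdname BeetleExampleSet-accessors
setMethod("classCounts", "BeetleExampleSet", function(x) {
  lab <- x$label
  c(positive = sum(lab == 1L), negative = sum(lab == 0L))
})

setMethod("show", "BeetleExampleSet", function(object) {
  cc <- classCounts(object)
  yrs <- sort(unique(object$year))
  cat(sprintf("BeetleExampleSet: %d examples (%d positive, %.2f%%), %d target years",
              ncol(object), cc["positive"],
              if (ncol(object)) 100 * cc["positive"] / ncol(object) else 0,
              length(yrs)))
  if (length(yrs)) cat(sprintf(" (%d-%d)", min(yrs), max(yrs)))
  cat("\n  assay 'window': 361 codes/example + temperature + stage = 363 inputs\n")
  invisible(NULL)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive class = disturbed)\n")
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2,
              dimnames = list(observed = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(NULL)
})

setMethod("show", "MetricReport", function(object) {
  v <- c(accuracy = object@accuracy, precision = object@precision,
         recall = object@recall, F1 = object@f1,
         conditionalKappa = object@conditionalKappa,
         trueSkillStatistic = object@trueSkillStatistic)
  cat("MetricReport\n")
  print(round(v, 4))
  invisible(NULL)
})

setMethod("show", "TrainedClassifier", function(object) {
  cfg <- object@config
  cat(sprintf("TrainedClassifier: %d conv + %d dense layers, %s encoding\n",
              length(cfg@convChannels), length(cfg@denseWidths), cfg@encodeMode))
  if (nrow(object@history))
    cat(sprintf("  %d epochs trained; selected epoch %d (eval accuracy %.4f)\n",
                nrow(object@history), object@selectedEpoch,
                object@history$evalAccuracy[object@selectedEpoch]))
  cat(sprintf("  threshold: %s\n",
              if (is.na(object@threshold)) "uncalibrated" else
                format(object@threshold)))
  invisible(NULL)
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult\n")
  cat(sprintf("  test examples: %s; threshold %.3f\n",
              format(object@provenance$nTest), object@threshold))
  show(object@report)
  if (!is.na(object@gleichlaeufigkeit))
    cat(sprintf("  Gleichlaeufigkeit(observed, predicted): %.3f\n",
                object@gleichlaeufigkeit))
  invisible(NULL)
})

#' Predict attack probabilities for a set of examples
#'
#' Returns one probability of attack (the positive class) per example,
#' deterministically: dropout is disabled and batch normalization uses its
#' running (inference) statistics.
#'
#' @param object a fitted [TrainedClassifier] or [LinearBaseline].
#' @param examples a [BeetleExampleSet] with the encoding the model was
#'   fitted on.
#' @param ... unused.
#' @return numeric vector in [0,1], one value per example.
#' @export
setGeneric("predictProba", function(object, examples, ...)
  standardGeneric("predictProba"))
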