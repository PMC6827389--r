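#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## Window geometry used throughout: a 19 x 19 moving window (radius 9 cells,
## i.e. 270 m at the 30 m grain), so each example carries 361 window codes
## plus two auxiliary variables (temperature, outbreak stage) = 363 inputs.
.WINDOW <- 19L
.WRADIUS <- 9L
.STAGE_LEVELS <- c("background", "gradation", "culmination")

#' LandscapeSeries: aligned multi-year raster stack of an outbreak landscape
#'
#' Holds the four inputs of the risk pipeline on a common grid: a binary
#' potential-host map (1 = cell contains mature host trees), one binary attack
#' map per calendar year (1 = cell mapped as beetle-killed that year), a
#' long-term mean annual temperature surface (degrees C), and the annual
#' regional disturbed-timber volume series used to classify outbreak stages.
#'
#' Grids are stored row-major as base matrices with (row, col) 1-based
#' indexing; georeferencing travels as opaque metadata in `geo`.
#'
#' @slot host integer matrix in \{0,1\}; NA is treated as non-host.
#' @slot attacks integer array (nrow x ncol x n_years) in \{0,1\}.
#' @slot temperature numeric matrix, finite on all host cells.
#' @slot regionalVolume named numeric vector (names = years); must cover at
#'   least the attack-map year range.
#' @slot years consecutive integer year labels, one per attack layer.
#' @slot cellSize cell edge length in metres (30 in the study system).
#' @slot geo opaque georeferencing metadata (e.g. ASCII-grid corner coords).
#'
#' @seealso [readLandscape()], [simulateOutbreak()], [buildExamples()]
#' @export
setClass("LandscapeSeries",
  representation(
    host = "matrix",
    attacks = "array",
    temperature = "matrix",
    regionalVolume = "numeric",
    years = "integer",
    cellSize = "numeric",
    geo = "list"
  )
)

setValidity("LandscapeSeries", function(object) {
  msg <- character()
  d <- dim(object@host)
  if (!identical(dim(object@temperature), d))
    msg <- c(msg, "temperature grid dimensions differ from host grid")
  da <- dim(object@attacks)
  if (length(da) != 3L || !identical(da[1:2], d))
    msg <- c(msg, "attack stack dimensions differ from host grid")
  ny <- length(object@years)
  if (length(da) == 3L && da[3] != ny)
    msg <- c(msg, "number of attack layers differs from length(years)")
  if (ny > 1L && !all(diff(object@years) == 1L))
    msg <- c(msg, "years are not consecutive")
  av <- object@attacks
  bad <- which(!(av %in% c(0L, 1L)))
  if (length(bad))
    msg <- c(msg, sprintf("attack maps must be binary; first offending index %d (value %s)",
                          bad[1], format(av[bad[1]])))
  hostIdx <- which(object@host == 1L)
  if (length(hostIdx) && any(!is.finite(object@temperature[hostIdx])))
    msg <- c(msg, "temperature is not finite on all host cells")
  vy <- suppressWarnings(as.integer(names(object@regionalVolume)))
  if (anyNA(vy))
    msg <- c(msg, "regionalVolume must be named by year")
  else if (ny && !all(object@years %in% vy))
    msg <- c(msg, "regionalVolume does not cover all attack-map years")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' StageSeries: regional outbreak-stage classification per year
#'
#' Years are partitioned into three population phases — background (endemic),
#' gradation (build-up) and culmination (peak) — by comparing each year's
#' regional disturbed-timber volume against the 33rd and 66th percentile of
#' the series; volumes at or below a cutoff fall in the lower class.
#'
#' @slot years integer year labels.
#' @slot stages factor with levels background < gradation < culmination
#'   (mapping configurable in [classifyOutbreakStages()]).
#' @slot cutoffs numeric length-2: the fitted 33rd/66th percentile cutoffs.
#' @slot volumes the volume series the cutoffs were fitted on.
#' @export
setClass("StageSeries",
  representation(years = "integer", stages = "factor",
                 cutoffs = "numeric", volumes = "numeric"))

setValidity("StageSeries", function(object) {
  msg <- character()
  if (length(object@years) != length(object@stages))
    msg <- c(msg, "years and stages lengths differ")
  if (length(object@cutoffs) != 2L || is.unsorted(object@cutoffs))
    msg <- c(msg, "cutoffs must be two non-decreasing values")
  if (length(msg)) msg else TRUE
})

#' BeetleExampleSet: the encoded example set as a SummarizedExperiment
#'
#' One column per focal cell-year. The single assay `"window"` is a 361 x n
#' integer matrix holding the column-major flattened 19 x 19 neighborhood
#' codes (0 = non-host, 1 = host not recently attacked, 2 = attacked two
#' years before the target year, 3 = attacked the year before; the more
#' recent attack wins). `colData` carries the auxiliary predictors and
#' provenance: `label` (focal cell attacked in the target year), `year`,
#' `row`, `col`, `temperature` (degrees C, unstandardized) and `stage`
#' (outbreak stage of the year preceding the target year).
#'
#' Flattening a window and appending the two auxiliaries gives exactly
#' 361 + 2 = 363 input variables per example.
#'
#' @seealso [buildExamples()], [splitByYears()], [splitRandom()]
#' @export
setClass("BeetleExampleSet", contains = "SummarizedExperiment")

setValidity("BeetleExampleSet", function(object) {
  msg <- character()
  if (!"window" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'window' is required")
  else if (nrow(object) != .WINDOW^2)
    msg <- c(msg, sprintf("assay 'window' must have %d rows", .WINDOW^2))
  need <- c("label", "year", "row", "col", "temperature", "stage")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    lab <- object$label
    if (any(!lab %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
    if (!identical(levels(object$stage), .STAGE_LEVELS))
      msg <- c(msg, "stage must be a factor with levels background/gradation/culmination")
  }
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: integer 2x2 classification counts
#'
#' "Disturbed" (attacked) is the positive class.
#'
#' @slot tp,tn,fp,fn non-negative integer counts; their sum N must be > 0.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4L || anyNA(v) || any(v < 0L))
    return("tp, tn, fp, fn must be single non-negative integers")
  if (sum(as.double(v)) <= 0) return("total count N must be positive")
  TRUE
})

#' MetricReport: the six evaluation statistics for a binary disturbance map
#'
#' Computed from a [ConfusionMatrix] in double precision. Conditional Kappa
#' and the True Skill Statistic follow the precision-based forms used in the
#' source analysis (TSS = precision + negative predictive value - 1); the
#' textbook sensitivity/specificity forms are carried in `extras`
#' (`tssSensSpec`, `npv`, `specificity`). Degenerate denominators yield NaN,
#' never an error.
#'
#' @slot accuracy,precision,recall,f1 numerics in [0,1] (or NaN).
#' @slot conditionalKappa,trueSkillStatistic numerics in [-1,1] (or NaN).
#' @slot extras named list of auxiliary statistics.
#' @export
setClass("MetricReport",
  representation(accuracy = "numeric", precision = "numeric", recall = "numeric",
                 f1 = "numeric", conditionalKappa = "numeric",
                 trueSkillStatistic = "numeric", extras = "list"))

#' ModelConfig: architecture and training hyper-parameters
#'
#' Defaults describe the reference architecture: five same-padded
#' convolution layers (3 x 3 kernels, strides 1-2-1-2-1 shrinking the
#' 19 x 19 window to 5 x 5) followed by five fully connected layers and a
#' two-unit softmax, trained with categorical cross entropy, weight decay,
#' dropout and batch normalization for 60 epochs. Every value is
#' overridable; tests and desk-scale runs use miniature configs.
#'
#' @slot convChannels integer vector, output channels per convolution layer.
#' @slot convStrides integer vector, stride per convolution layer.
#' @slot kernelSize single integer, square kernel edge.
#' @slot denseWidths integer vector, width per fully connected layer.
#' @slot dropoutRate dropout probability on dense layers, in [0,1).
#' @slot weightDecay L2 penalty coefficient on weights.
#' @slot batchNorm logical, batch normalization after conv/dense layers.
#' @slot learningRate,batchSize,epochs optimizer settings.
#' @slot optimizer `"adam"` or `"sgd"` (momentum 0.9).
#' @slot encodeMode `"ordinal"` (one channel of cell codes 0..3) or
#'   `"channels"` (three binary planes: host, attacked t-1, attacked t-2).
#' @slot classWeight positive-class weight (1 = no reweighting, the default).
#' @slot seed integer RNG seed for initialization and batching.
#' @export
setClass("ModelConfig",
  representation(convChannels = "integer", convStrides = "integer",
                 kernelSize = "integer", denseWidths = "integer",
                 dropoutRate = "numeric", weightDecay = "numeric",
                 batchNorm = "logical", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer",
                 optimizer = "character", encodeMode = "character",
                 classWeight = "numeric", seed = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@convChannels) != length(object@convStrides))
    msg <- c(msg, "convChannels and convStrides lengths differ")
  if (length(object@convChannels) < 1L || length(object@denseWidths) < 1L)
    msg <- c(msg, "need at least one convolution and one dense layer")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (!object@encodeMode %in% c("ordinal", "channels"))
    msg <- c(msg, "encodeMode must be 'ordinal' or 'channels'")
  if (object@kernelSize < 1L || object@kernelSize %% 2L == 0L)
    msg <- c(msg, "kernelSize must be a positive odd integer")
  if (any(object@convStrides < 1L)) msg <- c(msg, "strides must be >= 1")
  if (object@classWeight <= 0) msg <- c(msg, "classWeight must be positive")
  if (length(msg)) msg else TRUE
})

#' TrainedClassifier: a fitted hybrid CNN with its history and threshold
#'
#' @slot config the [ModelConfig] used.
#' @slot net list of fitted layer parameters (weights of the epoch with the
#'   highest evaluation accuracy).
#' @slot history data.frame with one row per epoch: `epoch`, `trainLoss`,
#'   `evalAccuracy`.
#' @slot selectedEpoch 1-based index of the best-evaluation-accuracy epoch.
#' @slot threshold calibrated classification threshold in [0,1] (NA until
#'   [selectThreshold()] / the experiment drivers set it).
#' @slot tempStats training-set mean and sd used to standardize temperature.
#' @export
setClass("TrainedClassifier",
  representation(config = "ModelConfig", net = "list", history = "data.frame",
                 selectedEpoch = "integer", threshold = "numeric",
                 tempStats = "numeric"))

setValidity("TrainedClassifier", function(object) {
  h <- object@history
  msg <- character()
  if (nrow(h) && object@selectedEpoch != which.max(h$evalAccuracy))
    msg <- c(msg, "selectedEpoch must be the argmax of evaluation accuracy")
  th <- object@threshold
  if (length(th) != 1L || (!is.na(th) && (th < 0 || th > 1)))
    msg <- c(msg, "threshold must be a single value in [0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' LinearBaseline: ridge-regularized logistic model on the flattened inputs
#'
#' A single linear (logistic) model over the 361 window codes plus the
#' standardized temperature and one-hot outbreak stage, as a floor against
#' which the convolutional model is compared.
#'
#' @slot fit the underlying glmnet fit.
#' @slot lambda the ridge penalty used.
#' @slot threshold calibrated threshold in [0,1] or NA.
#' @slot tempStats training-set temperature mean/sd.
#' @slot encodeMode window encoding used at fit time.
#' @export
setClass("LinearBaseline",
  representation(fit = "ANY", lambda = "numeric", threshold = "numeric",
                 tempStats = "numeric", encodeMode = "character"))

#' ExperimentResult: everything one experiment run produces
#'
#' @slot report pooled [MetricReport] over the test set.
#' @slot threshold the training-set-calibrated threshold used.
#' @slot perYearReports named list of per-target-year [MetricReport]s.
#' @slot annualSeries data.frame `year`, `observedHa`, `predictedHa`
#'   (positive-cell counts times the cell area, 0.09 ha at 30 m).
#' @slot probabilityMaps named list (by year) of probability matrices with
#'   NA on cells that were not scored.
#' @slot gleichlaeufigkeit sign-agreement of the observed and predicted
#'   annual series (NA for designs where it is not computed).
#' @slot classifier the fitted [TrainedClassifier].
#' @slot provenance list: config, seed, split description, dataset digest.
#' @export
setClass("ExperimentResult",
  representation(report = "MetricReport", threshold = "numeric",
                 perYearReports = "list", annualSeries = "data.frame",
                 probabilityMaps = "list", gleichlaeufigkeit = "numeric",
                 classifier = "ANY", provenance = "list"))

#' SimulationConfig: parameters of the synthetic contagious outbreak process
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' spatially autocorrelated host map, a smooth temperature gradient, local
#' two-year attack memory (contagion through an exponential dispersal kernel
#' truncated at 9 cells = 270 m), a regional forcing producing multi-year
#' outbreak waves, and a disturbed-volume series derived from attack counts.
#' Defaults target the study conditions: ~3.5% of cell-years attacked and
#' two outbreak waves over 14 years on a 100 x 100 grid.
#'
#' @slot nRows,nCols,nYears grid and series dimensions.
#' @slot hostFraction target share of host cells (0.6 by default, matching
#'   the study landscape's host share).
#' @slot hostSmoothingScale Gaussian smoothing sd (cells) of the host noise
#'   field; larger = coarser host patches.
#' @slot tempRange min/max of the north-south mean-temperature gradient (C).
#' @slot tempNoiseSd sd of cell-level temperature noise (C).
#' @slot baselineLogit intercept of the attack logit.
#' @slot wRecent,wOlder effect of the kernel-weighted fraction of neighbors
#'   attacked one / two years earlier.
#' @slot wTemp effect per degree C of (temperature - landscape mean).
#' @slot kernelRadius truncation radius of the dispersal kernel (cells).
#' @slot kernelScale e-folding distance of the kernel (cells).
#' @slot forcing per-year additive logit (regional wave signal); length
#'   nYears. Empty = default two-peak profile.
#' @slot killHosts if TRUE an attacked cell leaves the host pool for good.
#' @slot volumePerCell disturbed timber volume per attacked cell (m3).
#' @slot volumeNoiseSd sd of the lognormal observation noise on volumes.
#' @slot startYear first calendar year label.
#' @slot seed root RNG seed; components draw from named substreams.
#' @export
setClass("SimulationConfig",
  representation(nRows = "integer", nCols = "integer", nYears = "integer",
                 hostFraction = "numeric", hostSmoothingScale = "numeric",
                 tempRange = "numeric", tempNoiseSd = "numeric",
                 baselineLogit = "numeric", wRecent = "numeric",
                 wOlder = "numeric", wTemp = "numeric",
                 kernelRadius = "integer", kernelScale = "numeric",
                 forcing = "numeric", killHosts = "logical",
                 volumePerCell = "numeric", volumeNoiseSd = "numeric",
                 startYear = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nYears < 4L) msg <- c(msg, "nYears must be >= 4")
  if (object@hostFraction <= 0 || object@hostFraction > 1)
    msg <- c(msg, "hostFraction must be in (0, 1]")
  if (length(object@tempRange) != 2L)
    msg <- c(msg, "tempRange must be length 2")
  if (length(object@forcing) && length(object@forcing) != object@nYears)
    msg <- c(msg, "forcing must be empty or of length nYears")
  if (object@kernelRadius < 1L) msg <- c(msg, "kernelRadius must be >= 1")
  if (length(msg)) msg else TRUE
})
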