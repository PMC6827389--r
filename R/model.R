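#' @include AllClasses.R AllGenerics.R nnet-engine.R
NULL

#' Construct a model configuration
#'
#' The default describes the reference architecture: five same-padded
#' 3 x 3 convolution layers (strides 1-2-1-2-1 shrink the 19 x 19 window
#' to 5 x 5) followed by five fully connected layers and a two-unit
#' softmax, trained with categorical cross entropy plus weight decay,
#' dropout and batch normalization for 60 epochs. The printed source of
#' the architecture leaves kernel sizes, widths, optimizer and rates
#' unstated, so these defaults were fixed once on synthetic data and are
#' all overridable. Pooling layers are deliberately absent: a 19 x 19
#' input leaves little room for downsampling, so strided convolutions do
#' the shrinking.
#'
#' @param convChannels output channels per convolution layer.
#' @param convStrides stride per convolution layer (same length).
#' @param kernelSize odd kernel edge length.
#' @param denseWidths widths of the fully connected layers.
#' @param dropoutRate dropout probability on dense layers.
#' @param weightDecay L2 coefficient on weights.
#' @param batchNorm use batch normalization.
#' @param learningRate,batchSize,epochs optimizer settings.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param encodeMode `"ordinal"` (codes 0..3 in one channel) or
#'   `"channels"` (host / attacked t-1 / attacked t-2 binary planes).
#' @param classWeight positive-class loss weight (1 = none, the default:
#'   the source protocol uses no reweighting).
#' @param seed RNG seed for initialization and batch order.
#' @return a validated [ModelConfig].
#' @export
modelConfig <- function(convChannels = c(16L, 16L, 32L, 32L, 64L),
                        convStrides = c(1L, 2L, 1L, 2L, 1L),
                        kernelSize = 3L,
                        denseWidths = c(256L, 128L, 64L, 32L, 16L),
                        dropoutRate = 0.3, weightDecay = 1e-4,
                        batchNorm = TRUE, learningRate = 1e-3,
                        batchSize = 128L, epochs = 60L,
                        optimizer = "adam", encodeMode = "ordinal",
                        classWeight = 1, seed = 42L) {
  methods::new("ModelConfig",
               convChannels = as.integer(convChannels),
               convStrides = as.integer(convStrides),
               kernelSize = as.integer(kernelSize),
               denseWidths = as.integer(denseWidths),
               dropoutRate = dropoutRate, weightDecay = weightDecay,
               batchNorm = batchNorm, learningRate = learningRate,
               batchSize = as.integer(batchSize), epochs = as.integer(epochs),
               optimizer = optimizer, encodeMode = encodeMode,
               classWeight = classWeight, seed = as.integer(seed))
}

#' A small configuration for desk-scale training
#'
#' Two convolution and two dense layers; appropriate for simulated
#' landscapes and unit tests where the full reference architecture would
#' be wastefully large.
#'
#' @param ... overrides passed to [modelConfig()].
#' @return a [ModelConfig].
#' @export
smallModelConfig <- function(...) {
  args <- list(convChannels = c(8L, 16L), convStrides = c(2L, 2L),
               denseWidths = c(64L, 32L), dropoutRate = 0.2,
               batchSize = 256L, epochs = 10L, learningRate = 2e-3)
  args[names(list(...))] <- list(...)
  do.call(modelConfig, args)
}

## colData -> engine tensors. Temperature is standardized with the
## *training* mean/sd; the stage enters as a 3-level one-hot.
.tensorData <- function(examples, tempStats) {
  codes <- t(exampleWindows(examples))
  st <- examples$stage
  onehot <- matrix(0, length(st), 3L)
  onehot[cbind(seq_along(st), as.integer(st))] <- 1
  tz <- (examples$temperature - tempStats[1]) / tempStats[2]
  list(codes = codes, aux = cbind(tz, onehot),
       y = as.integer(examples$label))
}

.tempStats <- function(examples) {
  m <- mean(examples$temperature)
  s <- stats::sd(examples$temperature)
  if (!is.finite(s) || s == 0) s <- 1
  c(mean = m, sd = s)
}

#' Build an (untrained) hybrid convolutional classifier
#'
#' The architecture has two input branches: the convolutional branch
#' consumes the 19 x 19 window (one ordinal channel, or three binary
#' channels), and its flattened output is concatenated with the two
#' auxiliary inputs (standardized temperature and the one-hot outbreak
#' stage) before the fully connected stack; the output is a two-unit
#' softmax trained with categorical cross entropy. Initialization is
#' He-scaled Gaussian, fully determined by `config@seed`: two builds from
#' the same config are bitwise identical.
#'
#' @param config a [ModelConfig].
#' @return an untrained [TrainedClassifier] (empty history, NA threshold).
#' @export
buildClassifier <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  Cin <- if (config@encodeMode == "ordinal") 1L else 3L
  net <- .initLayers(config, Cin, nAux = 4L)
  methods::new("TrainedClassifier", config = config, net = net,
               history = data.frame(epoch = integer(), trainLoss = numeric(),
                                    evalAccuracy = numeric()),
               selectedEpoch = 0L, threshold = NA_real_,
               tempStats = c(mean = 0, sd = 1))
}

#' Number of trainable parameters of a classifier
#'
#' @param classifier a [TrainedClassifier].
#' @return integer count of weights, biases and batch-norm parameters.
#' @export
parameterCount <- function(classifier) {
  sum(vapply(classifier@net$layers, function(layer) {
    n <- length(layer$W) + length(layer$b)
    if (isTRUE(layer$bn)) n <- n + length(layer$gamma) + length(layer$beta)
    n
  }, 0))
}

#' Train the classifier
#'
#' Mini-batch training with the configured optimizer for `config@epochs`
#' epochs. After each epoch the classification accuracy on `evalSet` is
#' recorded, and the returned weights are those of the epoch with the
#' highest evaluation accuracy — replicating the published protocol of
#' selecting the best test-set epoch. (Pass a carved-out validation split
#' as `evalSet` for the leak-free variant.) Fully reproducible for a
#' fixed seed under a deterministic single-threaded BLAS.
#'
#' @param classifier an untrained or trained [TrainedClassifier] (training
#'   starts from its current weights).
#' @param trainSet,evalSet [BeetleExampleSet]s; the training set must
#'   contain both classes.
#' @return a [TrainedClassifier] with history, selected epoch and weights.
#' @examples
#' \donttest{
#' fx <- makeFixture("tiny", seed = 11)
#' es <- buildExamples(fx$series)
#' sp <- splitRandom(es, 0.25, seed = 1)
#' cfg <- smallModelConfig(epochs = 2L)
#' fit <- trainClassifier(buildClassifier(cfg), sp$train, sp$test)
#' }
#' @export
trainClassifier <- function(classifier, trainSet, evalSet) {
  stopifnot(methods::is(classifier, "TrainedClassifier"))
  config <- classifier@config
  if (length(unique(trainSet$label)) < 2L)
    stop("degenerate data: training set contains a single class")
  tempStats <- .tempStats(trainSet)
  train <- .tensorData(trainSet, tempStats)
  eval <- .tensorData(evalSet, tempStats)
  set.seed(config@seed)
  res <- .engineTrain(classifier@net, config, train, eval)
  methods::new("TrainedClassifier", config = config, net = res$net,
               history = res$history,
               selectedEpoch = as.integer(res$selectedEpoch),
               threshold = classifier@threshold, tempStats = tempStats)
}

#' @rdname predictProba
setMethod("predictProba", "TrainedClassifier", function(object, examples, ...) {
  if (nrow(examples) != .WINDOW^2)
    stop("schema error: examples do not carry 19 x 19 windows")
  d <- .tensorData(examples, object@tempStats)
  .enginePredict(object@net, d$codes, d$aux, object@config@encodeMode)
})

#' Fit the linear (logistic) baseline
#'
#' A single ridge-regularized logistic regression on the flattened inputs
#' — the 361 window codes plus standardized temperature and one-hot stage
#' — mirroring the generalized-linear-model comparison against which the
#' network's extra capacity is judged. The tiny ridge penalty keeps the
#' fit defined on separable data.
#'
#' @param trainSet a [BeetleExampleSet] with both classes present.
#' @param lambda ridge penalty at which coefficients are extracted.
#' @return a [LinearBaseline]; use [predictProba()] to score examples.
#' @export
fitLinearBaseline <- function(trainSet, lambda = 1e-4) {
  if (length(unique(trainSet$label)) < 2L)
    stop("degenerate data: training set contains a single class")
  tempStats <- .tempStats(trainSet)
  d <- .tensorData(trainSet, tempStats)
  x <- cbind(d$codes / 3, d$aux)
  fit <- glmnet::glmnet(x, factor(d$y, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = c(0.1, 0.01, 0.001, lambda),
                        standardize = FALSE)
  methods::new("LinearBaseline", fit = fit, lambda = lambda,
               threshold = NA_real_, tempStats = tempStats,
               encodeMode = "ordinal")
}

#' @rdname predictProba
setMethod("predictProba", "LinearBaseline", function(object, examples, ...) {
  if (nrow(examples) != .WINDOW^2)
    stop("schema error: examples do not carry 19 x 19 windows")
  d <- .tensorData(examples, object@tempStats)
  x <- cbind(d$codes / 3, d$aux)
  as.numeric(stats::predict(object@fit, newx = x, s = object@lambda,
                            type = "response"))
})

#' Set the calibrated threshold on a classifier
#'
#' @param classifier a [TrainedClassifier] or [LinearBaseline].
#' @param threshold probability threshold in [0,1].
#' @return the classifier with its threshold slot set.
#' @export
setThreshold <- function(classifier, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  classifier@threshold <- as.numeric(threshold)
  classifier
}
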