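#' @include AllClasses.R AllGenerics.R
NULL

#' Cross-tabulate labels against binary predictions
#'
#' Standard 2 x 2 confusion counts with "disturbed" (attacked, 1) as the
#' positive class.
#'
#' @param labels observed 0/1 vector.
#' @param predictions predicted 0/1 vector of the same length.
#' @return a [ConfusionMatrix].
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions have different lengths (",
         length(labels), " vs ", length(predictions), ")")
  l <- as.integer(labels); p <- as.integer(predictions)
  if (any(!l %in% c(0L, 1L)) || any(!p %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  methods::new("ConfusionMatrix",
               tp = sum(l == 1L & p == 1L), tn = sum(l == 0L & p == 0L),
               fp = sum(l == 0L & p == 1L), fn = sum(l == 1L & p == 0L))
}

.safeDiv <- function(num, den) if (den == 0) NaN else num / den

#' Compute the six evaluation statistics from a confusion matrix
#'
#' In the notation tp/tn/fp/fn, N = tp+tn+fp+fn:
#' accuracy = (tn+tp)/N; precision = tp/(tp+fp); recall = tp/(tp+fn);
#' F1 = 2 pr re / (pr + re);
#' Conditional Kappa = (precision - (tp+fn)/N) / (1 - (tp+fn)/N), i.e.
#' precision corrected for the positive-class prevalence;
#' True Skill Statistic = precision + tn/(tn+fn) - 1, the precision /
#' negative-predictive-value form used in the source analysis. Note that
#' much of the species-distribution literature defines TSS as
#' sensitivity + specificity - 1; that conventional form (and specificity
#' and NPV themselves) is reported under `extras` for comparison, but the
#' headline `trueSkillStatistic` slot is the precision-based form.
#'
#' All statistics are computed in double precision. A zero denominator
#' yields NaN rather than an error, so degenerate test sets (e.g. a year
#' with no attacks) flow through reporting.
#'
#' @param cm a [ConfusionMatrix].
#' @return a [MetricReport].
#' @examples
#' metricReport(backsolveConfusion(292559, 0.966, 0.652, 0.392))
#' @export
metricReport <- function(cm) {
  stopifnot(methods::is(cm, "ConfusionMatrix"))
  tp <- as.double(cm@tp); tn <- as.double(cm@tn)
  fp <- as.double(cm@fp); fn <- as.double(cm@fn)
  N <- tp + tn + fp + fn
  acc <- .safeDiv(tn + tp, N)
  pr <- .safeDiv(tp, tp + fp)
  re <- .safeDiv(tp, tp + fn)
  f1 <- if (is.nan(pr) || is.nan(re)) NaN else .safeDiv(2 * pr * re, pr + re)
  prev <- .safeDiv(tp + fn, N)
  ck <- if (is.nan(pr)) NaN else .safeDiv(pr - prev, 1 - prev)
  npv <- .safeDiv(tn, tn + fn)
  tss <- if (is.nan(pr) || is.nan(npv)) NaN else pr + npv - 1
  spec <- .safeDiv(tn, tn + fp)
  tssConv <- if (is.nan(re) || is.nan(spec)) NaN else re + spec - 1
  methods::new("MetricReport", accuracy = acc, precision = pr, recall = re,
               f1 = f1, conditionalKappa = ck, trueSkillStatistic = tss,
               extras = list(npv = npv, specificity = spec,
                             tssSensSpec = tssConv, prevalence = prev,
                             n = N))
}

#' Recover a confusion matrix from N, accuracy, precision and recall
#'
#' Algebraic inversion of the metric definitions: with P = tp + fn the
#' actual-positive count, the error count N (1 - accuracy) = fn + fp =
#' P (1 - recall) + P recall (1 - precision)/precision, which is solved
#' for P; then tp = recall P, fp = tp (1 - precision)/precision, tn is the
#' remainder. Counts are rounded to the nearest integers and the forward
#' metrics must reproduce the inputs within `tol`, otherwise the inputs
#' are inconsistent and an error is raised. This turns published
#' (N, accuracy, precision, recall) rows into exact testable matrices.
#'
#' @param N total example count.
#' @param accuracy,precision,recall the published values.
#' @param tol forward-check tolerance on each reproduced metric.
#' @return a [ConfusionMatrix].
#' @examples
#' backsolveConfusion(292559, 0.966, 0.652, 0.392)
#' @export
backsolveConfusion <- function(N, accuracy, precision, recall, tol = 1e-3) {
  stopifnot(N > 0, accuracy >= 0, accuracy <= 1,
            precision > 0, precision <= 1, recall >= 0, recall <= 1)
  den <- (1 - recall) + recall * (1 - precision) / precision
  P <- if (den == 0) 0 else N * (1 - accuracy) / den
  if (accuracy == 1) P <- NA  # errorless: prevalence unidentified w/o more info
  if (is.na(P)) {
    # perfect classifier: any split works; put all mass consistent w/ recall=1
    tp <- round(N * 0.5); fn <- 0; fp <- 0; tn <- N - tp
  } else {
    tp <- round(recall * P)
    fn <- round(P) - tp
    fp <- round(tp * (1 - precision) / precision)
    tn <- N - tp - fn - fp
  }
  if (min(tp, tn, fp, fn) < 0)
    stop("inconsistent inputs: back-solved counts are negative")
  cm <- methods::new("ConfusionMatrix", tp = as.integer(tp),
                     tn = as.integer(tn), fp = as.integer(fp),
                     fn = as.integer(fn))
  rep <- metricReport(cm)
  ok <- isTRUE(abs(rep@accuracy - accuracy) <= tol &&
    abs(rep@precision - precision) <= tol &&
    abs(rep@recall - recall) <= tol)
  if (!ok)
    stop("inconsistent inputs: forward metrics of the back-solved matrix ",
         sprintf("(acc %.4f, pr %.4f, re %.4f) do not reproduce the inputs",
                 rep@accuracy, rep@precision, rep@recall),
         " within tolerance ", tol)
  cm
}

#' Select the classification threshold maximizing F1
#'
#' Scans a fixed grid of thresholds from 0 to 1 in steps of 0.001,
#' classifies `probability >= threshold` as positive, and returns the
#' threshold with the highest F1; ties are broken toward the larger
#' threshold (the more conservative classifier). The threshold is always
#' calibrated on training data.
#'
#' @param probabilities predicted attack probabilities in [0,1].
#' @param labels observed 0/1 labels (both classes must be present).
#' @param step grid step (default 0.001).
#' @return the selected threshold, with attribute `"f1"`.
#' @export
selectThreshold <- function(probabilities, labels, step = 0.001) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate data: both classes must be present to calibrate")
  stopifnot(length(probabilities) == length(labels))
  grid <- seq(0, 1, by = step)
  o <- order(probabilities)
  ps <- probabilities[o]
  ls <- labels[o]
  nPos <- sum(ls)
  # positives among examples with prob >= t: suffix sums over the sorted order
  sufPos <- rev(cumsum(rev(ls)))
  n <- length(ls)
  # index of first sorted prob >= t
  first <- n - findInterval(grid - 1e-12, ps)  # count of ps >= t
  tp <- ifelse(first > 0, sufPos[n - first + 1], 0)
  predPos <- first
  fp <- predPos - tp
  fn <- nPos - tp
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  best <- max(f1)
  th <- grid[max(which(f1 == best))]
  attr(th, "f1") <- best
  th
}

#' Gleichlaeufigkeit: sign agreement of two time series
#'
#' A dendrochronology statistic for the similarity of two series based on
#' the sign of consecutive-year differences. Each step gets
#' G_i = +1/2, 0, -1/2 for a positive, zero or negative difference, and
#' G = (1/(n-1)) sum |G_i(x) + G_i(y)|: 1 when the series always move in
#' the same direction, 0 when they always move oppositely.
#'
#' @param x,y numeric series of equal length n >= 2.
#' @return numeric in [0, 1].
#' @examples
#' gleichlaeufigkeit(c(1, 2, 1, 3), c(2, 1, 3, 4))  # 1/3
#' @export
gleichlaeufigkeit <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2L) stop("insufficient data: need at least 2 points")
  gx <- sign(diff(x)) / 2
  gy <- sign(diff(y)) / 2
  mean(abs(gx + gy))
}
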