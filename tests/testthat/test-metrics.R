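test_that("confusion counts match a brute-force tally", {
  cm <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(c(cm@tp, cm@tn, cm@fp, cm@fn), c(2L, 1L, 0L, 0L))
  cm2 <- confusionCounts(c(1, 0), c(0, 0))
  expect_identical(c(cm2@fn, cm2@tn), c(1L, 1L))
  set.seed(101)
  labels <- rbinom(1000, 1, 0.3)
  preds <- rbinom(1000, 1, 0.5)
  cm3 <- confusionCounts(labels, preds)
  oracle <- bruteConfusion(labels, preds)
  expect_identical(c(tp = cm3@tp, tn = cm3@tn, fp = cm3@fp, fn = cm3@fn),
                   oracle)
  expect_error(confusionCounts(c(1, 0), c(1)), "lengths")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("the six statistics are computed as printed, NaN when degenerate", {
  perfect <- metricReport(methods::new("ConfusionMatrix", tp = 10L, tn = 90L,
                                       fp = 0L, fn = 0L))
  for (s in c("accuracy", "precision", "recall", "f1", "conditionalKappa",
              "trueSkillStatistic"))
    expect_equal(methods::slot(perfect, s), 1)

  # all-negative predictions: precision, F1, kappa, TSS undefined -> NaN
  deg <- metricReport(methods::new("ConfusionMatrix", tp = 0L, tn = 5L,
                                   fp = 0L, fn = 3L))
  expect_true(is.nan(deg@precision))
  expect_true(is.nan(deg@f1))
  expect_true(is.nan(deg@trueSkillStatistic))
  expect_equal(deg@accuracy, 5 / 8)

  # hand-checked matrix: metrics from their printed definitions
  cm <- methods::new("ConfusionMatrix", tp = 30L, tn = 50L, fp = 10L,
                     fn = 10L)
  r <- metricReport(cm)
  expect_equal(r@accuracy, 0.8)
  expect_equal(r@precision, 0.75)
  expect_equal(r@recall, 0.75)
  expect_equal(r@f1, 0.75)
  expect_equal(r@conditionalKappa, (0.75 - 0.4) / (1 - 0.4))
  expect_equal(r@trueSkillStatistic, 0.75 + 50 / 60 - 1)
  # conventional sensitivity+specificity form carried alongside
  expect_equal(r@extras$tssSensSpec, 0.75 + 50 / 60 - 1)
  # F1 equals the harmonic-mean identity whenever tp > 0
  expect_equal(r@f1, 2 * r@precision * r@recall / (r@precision + r@recall))
})

test_that("back-solving recovers arbitrary confusion matrices exactly", {
  set.seed(77)
  for (i in 1:50) {
    tp <- sample(1:5000, 1); fn <- sample(0:5000, 1)
    fp <- sample(0:5000, 1); tn <- sample(0:100000, 1)
    if (fp + fn == 0) fp <- 1   # errorless matrices are underdetermined
    r <- metricReport(methods::new("ConfusionMatrix", tp = as.integer(tp),
                                   tn = as.integer(tn), fp = as.integer(fp),
                                   fn = as.integer(fn)))
    N <- tp + tn + fp + fn
    back <- backsolveConfusion(N, r@accuracy, r@precision, r@recall)
    expect_identical(c(back@tp, back@tn, back@fp, back@fn),
                     as.integer(c(tp, tn, fp, fn)))
  }
  # perfect-classifier inputs admit fp = fn = 0
  p <- backsolveConfusion(100, 1, 1, 1)
  expect_identical(c(p@fp, p@fn), c(0L, 0L))
  expect_error(backsolveConfusion(1000, 0.99, 0.9, 0.2), "inconsistent")
})

test_that("threshold search maximizes F1 on the grid, ties to the right", {
  # perfectly separated: any threshold in (0.1, 0.9] is optimal -> 0.9
  pr <- c(rep(0.1, 20), rep(0.9, 10))
  lab <- c(rep(0, 20), rep(1, 10))
  th <- selectThreshold(pr, lab)
  expect_equal(as.numeric(th), 0.9)
  expect_equal(attr(th, "f1"), 1)

  # grid search equals exhaustive search over unique probabilities
  set.seed(303)
  p2 <- round(runif(200), 3)     # on-grid so resolutions coincide
  l2 <- rbinom(200, 1, plogis(4 * p2 - 2))
  if (length(unique(l2)) > 1) {
    th2 <- selectThreshold(p2, l2)
    expect_equal(attr(th2, "f1"),
                 bruteBestF1(p2, l2, sort(unique(c(0, p2, 1)))))
  }

  # all probabilities equal: threshold sits at that value, F1 = all-positive
  p3 <- rep(0.4, 30); l3 <- rbinom(30, 1, 0.5)
  th3 <- selectThreshold(p3, l3)
  expect_equal(as.numeric(th3), 0.4)
  expect_equal(attr(th3, "f1"),
               2 * sum(l3) / (2 * sum(l3) + sum(l3 == 0)))
  expect_error(selectThreshold(runif(5), rep(1, 5)), "degenerate")
})

test_that("gleichlaeufigkeit matches hand computation and its invariances", {
  expect_equal(gleichlaeufigkeit(c(1, 2, 1, 3), c(2, 1, 3, 4)), 1 / 3)
  expect_equal(gleichlaeufigkeit(1:7, (1:7)^2), 1)        # co-monotone
  expect_equal(gleichlaeufigkeit(1:5, 5:1), 0)            # anti-monotone
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(sample(2:15, 1)); y <- rnorm(length(x))
    expect_equal(gleichlaeufigkeit(x, y), bruteGleich(x, y))
    expect_equal(gleichlaeufigkeit(x, y), gleichlaeufigkeit(y, x))
    expect_equal(gleichlaeufigkeit(x + 3.7, y), gleichlaeufigkeit(x, y))
  }
  expect_error(gleichlaeufigkeit(1, 2), "insufficient")
  expect_error(gleichlaeufigkeit(1:3, 1:4), "lengths differ")
})

test_that("kappa and TSS are 1 only for error-free matrices, ~0 for noise", {
  set.seed(11)
  for (i in 1:20) {
    cm <- methods::new("ConfusionMatrix",
                       tp = sample(1:50, 1), tn = sample(1:50, 1),
                       fp = sample(0:50, 1), fn = sample(0:50, 1))
    r <- metricReport(cm)
    if (cm@fp == 0L && cm@fn == 0L) {
      expect_equal(r@conditionalKappa, 1)
      expect_equal(r@trueSkillStatistic, 1)
    } else {
      expect_lt(r@conditionalKappa, 1)
      expect_lt(r@trueSkillStatistic, 1)
    }
  }
  # label-shuffled predictions carry no skill
  for (seed in 1:3) {
    set.seed(seed)
    lab <- rbinom(10000, 1, 0.2)
    prd <- sample(lab)
    r <- metricReport(confusionCounts(lab, prd))
    expect_lt(abs(r@conditionalKappa), 0.05)
    expect_lt(abs(r@trueSkillStatistic), 0.05)
  }
})
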