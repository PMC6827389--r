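test_that("config validation rejects inconsistent architectures", {
  expect_error(modelConfig(convChannels = c(8L, 16L), convStrides = 2L),
               "lengths differ")
  expect_error(modelConfig(dropoutRate = 1), "dropoutRate")
  expect_error(modelConfig(kernelSize = 4L), "kernelSize")
  expect_error(modelConfig(optimizer = "lbfgs"), "optimizer")
  expect_error(modelConfig(encodeMode = "pixel"), "encodeMode")
})

test_that("builds are seeded: identical configs give bitwise-equal nets", {
  cfg <- smallModelConfig(seed = 123L)
  a <- buildClassifier(cfg)
  b <- buildClassifier(cfg)
  expect_identical(a@net, b@net)
  expect_gt(parameterCount(a), 0)
  d <- buildClassifier(smallModelConfig(seed = 124L))
  expect_false(identical(a@net, d@net))
})

test_that("softmax outputs are probabilities; duplicates score identically", {
  fx <- makeFixture("tiny", seed = 31L)
  es <- buildExamples(fx$series)[, 1:40]
  clf <- buildClassifier(smallModelConfig(seed = 5L))
  p <- predictProba(clf, es)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated example -> identical probability (deterministic inference)
  dup <- es[, c(7L, 7L)]
  pd <- predictProba(clf, dup)
  expect_identical(pd[1], pd[2])
  # untrained symmetric net on an uninformative input sits near 1/2
  expect_lt(abs(p[1] - 0.5), 0.2)
})

test_that("training is reproducible and selects the best-accuracy epoch", {
  fx <- makeFixture("tiny", seed = 17L)
  es <- buildExamples(fx$series)
  sp <- splitRandom(es, 0.3, seed = 1L)
  cfg <- smallModelConfig(epochs = 3L, convChannels = c(4L, 8L),
                          denseWidths = c(16L, 8L), seed = 2L)
  f1 <- trainClassifier(buildClassifier(cfg), sp$train, sp$test)
  f2 <- trainClassifier(buildClassifier(cfg), sp$train, sp$test)
  expect_identical(f1@history, f2@history)
  expect_identical(f1@net$layers, f2@net$layers)
  expect_identical(nrow(f1@history), 3L)
  expect_identical(f1@selectedEpoch, which.max(f1@history$evalAccuracy))
  expect_error(trainClassifier(buildClassifier(cfg),
                               sp$train[, sp$train$label == 0L], sp$test),
               "degenerate")
})

test_that("a separable rule is learned to perfection by net and baseline", {
  fx <- makeFixture("separable", seed = 4L)
  es <- buildExamples(fx$series, hostMortality = FALSE)
  # the preset's generating rule: label = (center-left code == 3)
  expect_identical(es$label,
                   as.integer(exampleWindows(es)[fx$expected$ruleIndex, ] == 3L))
  sp <- splitRandom(es, 0.3, seed = 2L)
  cfg <- smallModelConfig(epochs = 8L, seed = 1L)
  fit <- trainClassifier(buildClassifier(cfg), sp$train, sp$test)
  p <- predictProba(fit, sp$train)
  th <- selectThreshold(p, sp$train$label)
  expect_equal(mean((p >= th) == (sp$train$label == 1L)), 1)

  lb <- fitLinearBaseline(sp$train)
  pl <- predictProba(lb, sp$train)
  expect_equal(mean((pl >= 0.5) == (sp$train$label == 1L)), 1)
  # held out: both models generalize the deterministic rule
  expect_gt(attr(selectThreshold(predictProba(fit, sp$test),
                                 sp$test$label), "f1"), 0.95)
})

test_that("baseline predicts a constant on constant inputs", {
  fx <- makeFixture("tiny", seed = 9L)
  es <- buildExamples(fx$series)
  lb <- fitLinearBaseline(es)
  one <- es[, rep(3L, 5L)]
  expect_equal(diff(range(predictProba(lb, one))), 0)
})

test_that("label shuffling destroys held-out skill (negative control)", {
  ls <- simulateOutbreak(simulationConfig(nRows = 50L, nCols = 50L,
                                          nYears = 10L, seed = 21L))
  es <- buildExamples(ls)
  sp <- splitRandom(es, 0.4, seed = 3L)
  for (seed in 1:3) {
    shuffled <- sp$train
    set.seed(seed)
    shuffled$label <- sample(shuffled$label)
    cfg <- smallModelConfig(epochs = 3L, convChannels = c(4L, 8L),
                            denseWidths = c(16L, 8L), seed = seed)
    fit <- trainClassifier(buildClassifier(cfg), shuffled, sp$test)
    p <- predictProba(fit, sp$test)
    th <- selectThreshold(predictProba(fit, shuffled), shuffled$label)
    r <- metricReport(confusionCounts(sp$test$label,
                                      as.integer(p >= th)))
    tss <- r@trueSkillStatistic
    if (!is.nan(tss)) expect_lt(abs(tss), 0.1)
  }
})
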