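test_that("host maps hit the target fraction and are seeded", {
  cfg <- simulationConfig(nRows = 200L, nCols = 200L, hostFraction = 0.6,
                          seed = 12L)
  h <- generateHostMap(cfg)
  expect_gte(mean(h), 0.58); expect_lte(mean(h), 0.62)
  expect_identical(generateHostMap(cfg), h)
  h1 <- generateHostMap(simulationConfig(nRows = 40L, nCols = 40L,
                                         hostFraction = 1, seed = 1L))
  expect_true(all(h1 == 1L))
  # spatial autocorrelation: same-value neighbor share far above random
  agree <- mean(h[-1, ] == h[-200, ])
  expect_gt(agree, 0.8)
})

test_that("with no contagion, prevalence matches the configured logit", {
  for (seed in 1:3) {
    cfg <- simulationConfig(nRows = 60L, nCols = 60L, nYears = 6L,
                            wRecent = 0, wOlder = 0, wTemp = 0,
                            baselineLogit = qlogis(0.05),
                            forcing = rep(0, 6), killHosts = FALSE,
                            seed = seed)
    ls <- simulateOutbreak(cfg)
    nHost <- sum(hostMap(ls))
    rate <- sum(attackMaps(ls)) / (nHost * 6)
    # binomial error: ~sqrt(p(1-p)/n) with n = host cells x years
    expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / (nHost * 6)))
  }
})

test_that("two-peak forcing produces two outbreak waves", {
  fx <- makeFixture("two_wave", seed = 1L)
  counts <- apply(attackMaps(fx$series), 3, sum)
  peaks <- fx$expected$forcingPeaks
  # a local maximum within +-1 year of each forced peak, with a trough between
  w1 <- max(counts[(peaks[1] - 1):(peaks[1] + 1)])
  w2 <- max(counts[(peaks[2] - 1):(peaks[2] + 1)])
  trough <- min(counts[(peaks[1] + 1):(peaks[2] - 1)])
  expect_gt(w1, 1.2 * trough)
  expect_gt(w2, 2 * trough)
  # byte-identical under the same seed
  fx2 <- makeFixture("two_wave", seed = 1L)
  expect_identical(attackMaps(fx2$series), attackMaps(fx$series))
  expect_identical(regionalVolume(fx2$series), regionalVolume(fx$series))
})

test_that("killed hosts are never attacked twice", {
  for (seed in 1:3) {
    ls <- simulateOutbreak(simulationConfig(nRows = 40L, nCols = 40L,
                                            nYears = 8L, seed = seed))
    perCell <- apply(attackMaps(ls), c(1, 2), sum)
    expect_lte(max(perCell), 1L)
  }
})

test_that("prevalence responds monotonically to the baseline logit", {
  rates <- vapply(c(-8.5, -7.3, -6.1), function(bl) {
    ls <- simulateOutbreak(simulationConfig(nRows = 50L, nCols = 50L,
                                            nYears = 8L, baselineLogit = bl,
                                            seed = 6L))
    sum(attackMaps(ls)) / sum(hostMap(ls))
  }, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("stronger recent-attack contagion raises spatial autocorrelation", {
  joinCount <- function(a) {
    if (sum(a) < 2) return(0)
    mean(c(a[-1, ] * a[-nrow(a), ], a[, -1] * a[, -ncol(a)])) / mean(a)^2
  }
  jc <- sapply(1:5, function(seed) {
    vapply(c(0, 1.7), function(wr) {
      cfg <- simulationConfig(nRows = 60L, nCols = 60L, nYears = 7L,
                              wRecent = wr, seed = seed)
      ls <- simulateOutbreak(cfg)
      mean(apply(attackMaps(ls)[, , 4:7], 3, joinCount))
    }, 0)
  })
  expect_gt(mean(jc[2, ] - jc[1, ]), 0)
})

test_that("generative coefficient signs are recoverable by logistic fit", {
  hits <- vapply(1:20, function(seed) {
    cfg <- simulationConfig(nRows = 50L, nCols = 50L, nYears = 7L,
                            seed = seed)
    ls <- simulateOutbreak(cfg)
    kern <- BarkBeetleNet:::.dispersalKernel(cfg@kernelRadius,
                                             cfg@kernelScale)
    att <- attackMaps(ls); host <- hostMap(ls)
    rows <- list()
    prior <- matrix(0L, 50, 50)
    for (y in seq_len(2)) prior <- prior + att[, , y]
    for (y in 3:dim(att)[3]) {
      K1 <- BarkBeetleNet:::.conv2same(att[, , y - 1], kern)
      K2 <- BarkBeetleNet:::.conv2same(att[, , y - 2], kern)
      elig <- host == 1L & prior == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        y = att[, , y][elig], K1 = K1[elig], K2 = K2[elig],
        temp = temperatureMap(ls)[elig])
      prior <- prior + att[, , y]
    }
    df <- do.call(rbind, rows)
    fit <- suppressWarnings(glm(y ~ K1 + K2 + temp, family = binomial,
                                data = df))
    all(coef(fit)[c("K1", "K2", "temp")] > 0)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the null preset behaves as an iid negative control", {
  fx <- makeFixture("null", seed = 3L)
  counts <- apply(attackMaps(fx$series), 3, sum)
  nHost <- sum(hostMap(fx$series))
  expect_lt(abs(mean(counts / nHost) - 0.035), 0.01)
  # no year-over-year memory: attack maps are uncorrelated in time
  a <- attackMaps(fx$series)
  overlap <- vapply(2:dim(a)[3], function(y)
    sum(a[, , y] * a[, , y - 1]), 0)
  expected <- counts[-1] * counts[-length(counts)] / nHost
  expect_lt(abs(mean(overlap - expected)), 3 * sqrt(mean(expected)))
})
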