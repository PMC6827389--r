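test_that("outbreak stages follow tercile cutoffs with downward ties", {
  ss <- classifyOutbreakStages(1:9, 2001:2009)
  expect_identical(as.character(ss@stages),
                   rep(c("background", "gradation", "culmination"), each = 3))
  # constant series: every year at/below both cutoffs -> lowest class
  flat <- classifyOutbreakStages(rep(5, 6), 2001:2006)
  expect_true(all(flat@stages == "background"))
  expect_error(classifyOutbreakStages(c(1, 2), 2001:2002), "insufficient")
  # tercile-to-name mapping is configurable
  sw <- classifyOutbreakStages(1:9, 2001:2009,
                               mapping = c("background", "culmination",
                                           "gradation"))
  expect_identical(as.character(stageOf(sw, 2005)), "culmination")
  expect_error(stageOf(sw, 1990), "not in stage series")
})

test_that("window encoding marks recency, non-hosts and padding", {
  ls <- handLandscape()
  # all-non-host neighborhood: corner block is non-host, rest out of bounds
  w0 <- encodeWindow(ls, 2, 2, 2003)
  expect_identical(dim(w0), c(19L, 19L))
  # focal (6,6) in year 2003: left neighbor (6,5) attacked in 2002 (year-1)
  w <- encodeWindow(ls, 6, 6, 2003)
  expect_identical(w[10, 9], 3L)
  expect_identical(sum(w == 3L), 1L)
  # (9,9) attacked in 2001 (year-2): code 2 at offset (+3,+3)
  expect_identical(w[13, 13], 2L)
  # corner focal cell: window covers 10x10 in-bounds cells, 261 padded zeros
  wc <- encodeWindow(ls, 1, 1, 2003)
  expect_identical(sum(wc[1:9, ] == 0L) + sum(wc[10:19, 1:9] == 0L), 261L)
  expect_error(encodeWindow(ls, 0, 5, 2003), "bounds")
  expect_error(encodeWindow(ls, 5, 5, 2002), "two preceding")
})

test_that("host mortality removes killed cells from codes and focal set", {
  ls <- handLandscape()
  # (9,9) attacked in 2001; by target year 2004 it is dead -> code 0
  w <- encodeWindow(ls, 9, 9, 2004)
  expect_identical(w[10, 10], 0L)
  w2 <- encodeWindow(ls, 9, 9, 2004, hostMortality = FALSE)
  expect_identical(w2[10, 10], 1L)
  es <- buildExamples(ls)
  expect_false(any(es$row == 9 & es$col == 9 & es$year == 2004))
  esAll <- buildExamples(ls, hostMortality = FALSE)
  expect_true(any(esAll$row == 9 & esAll$col == 9 & esAll$year == 2004))
})

test_that("example sets carry 363 inputs and respect eligibility counts", {
  ls <- handLandscape()
  es <- buildExamples(ls)
  # 361 window codes + temperature + stage = 363 input variables
  expect_identical(nrow(es), 361L)
  flat <- c(exampleWindows(es)[, 1], es$temperature[1],
            as.integer(es$stage[1]))
  expect_length(flat, 363L)
  # target years: all years with two predecessors
  expect_identical(sort(unique(es$year)), c(2003L, 2004L))
  # year 2003: all 135 host cells eligible except the 2 previously attacked
  expect_identical(sum(es$year == 2003), 135L - 2L)
  # labels come from the target-year attack map
  hit <- es$label == 1L & es$year == 2003L
  expect_identical(sum(hit), 1L)
  expect_identical(c(es$row[hit], es$col[hit]), c(9L, 10L))
  expect_identical(unname(classCounts(es)),
                   c(sum(es$label), ncol(es) - sum(es$label)))
  # stage covariate is the stage of the preceding year
  ss <- classifyOutbreakStages(ls)
  expect_identical(as.character(unique(es$stage[es$year == 2003])),
                   as.character(stageOf(ss, 2002)))
})

test_that("window extraction is translation-consistent", {
  ls <- handLandscape()
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m) + dr, ncol(m) + dc)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  att <- array(0L, c(15, 15, 4))
  for (k in 1:4) att[, , k] <- shift(ls@attacks[, , k], 3L, 3L)
  ls2 <- methods::new("LandscapeSeries",
                      host = shift(ls@host, 3L, 3L), attacks = att,
                      temperature = matrix(6, 15, 15),
                      regionalVolume = ls@regionalVolume, years = ls@years,
                      cellSize = 30, geo = list())
  for (rc in list(c(6, 6), c(9, 9), c(4, 10))) {
    expect_identical(encodeWindow(ls2, rc[1] + 3L, rc[2] + 3L, 2003),
                     encodeWindow(ls, rc[1], rc[2], 2003))
  }
})

test_that("splits partition the example set without loss or duplication", {
  ls <- simulateOutbreak(simulationConfig(nRows = 25L, nCols = 25L,
                                          nYears = 6L, seed = 2L))
  es <- buildExamples(ls)
  sp <- splitByYears(es, 2003L)
  expect_identical(sort(unique(sp$test$year)), 2003L)
  expect_identical(ncol(sp$train) + ncol(sp$test), ncol(es))
  key <- function(x) paste(x$row, x$col, x$year)
  expect_identical(sort(c(key(sp$train), key(sp$test))), sort(key(es)))
  expect_error(splitByYears(es, 1999L), "not in the example set")
  expect_error(splitByYears(es, unique(es$year)), "train set empty")

  sr <- splitRandom(es, 0.2, seed = 7L)
  expect_identical(ncol(sr$test), as.integer(round(0.2 * ncol(es))))
  expect_identical(sort(c(key(sr$train), key(sr$test))), sort(key(es)))
  # reproducible under the same seed, different under another
  sr2 <- splitRandom(es, 0.2, seed = 7L)
  expect_identical(key(sr$test), key(sr2$test))
  sr3 <- splitRandom(es, 0.2, seed = 8L)
  expect_false(identical(key(sr$test), key(sr3$test)))
  expect_error(splitRandom(es, 1.2), "fraction")
})

test_that("a landscape with no attacks yields all-negative labels", {
  ls <- handLandscape()
  ls@attacks[] <- 0L
  es <- buildExamples(ls)
  expect_identical(sum(es$label), 0L)
  expect_identical(unname(classCounts(es)["positive"]), 0L)
})
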