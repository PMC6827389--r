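#' @include AllClasses.R AllGenerics.R
NULL

#' Classify years into regional outbreak stages
#'
#' Each year is assigned one of three population phases by comparing its
#' annual regional disturbed-timber volume against the 33rd and 66th
#' percentile of the volume series (linear interpolation between order
#' statistics, `quantile` type 7). Volumes at or below a cutoff fall in the
#' lower class, so a constant series is entirely in the lowest class.
#'
#' The default tercile-to-name mapping follows the ecological reading of
#' the phases: lowest = background (endemic), middle = gradation
#' (build-up), highest = culmination (peak). The mapping is configurable
#' because stage names are a labeling convention, not part of the
#' computation.
#'
#' @param volumes numeric volume series (or a [LandscapeSeries], whose
#'   regional volume series is used).
#' @param years integer year labels (ignored when `volumes` is a
#'   [LandscapeSeries]).
#' @param mapping character length-3: stage names for the lowest, middle and
#'   highest tercile.
#' @return a [StageSeries].
#' @examples
#' ss <- classifyOutbreakStages(c(10, 80, 200, 150, 30), 2001:2005)
#' stageOf(ss, 2003)
#' @export
classifyOutbreakStages <- function(volumes, years = NULL,
                                   mapping = c("background", "gradation",
                                               "culmination")) {
  if (methods::is(volumes, "LandscapeSeries")) {
    years <- as.integer(names(volumes@regionalVolume))
    volumes <- unname(volumes@regionalVolume)
  }
  if (length(volumes) < 3L)
    stop("insufficient data: need at least 3 years of volumes to fit terciles")
  if (is.null(years)) years <- seq_along(volumes)
  stopifnot(length(years) == length(volumes))
  stopifnot(length(mapping) == 3L, all(mapping %in% .STAGE_LEVELS))
  q <- stats::quantile(volumes, c(0.33, 0.66), type = 7, names = FALSE)
  tier <- 1L + (volumes > q[1]) + (volumes > q[2])   # ties go to lower class
  stages <- factor(mapping[tier], levels = .STAGE_LEVELS)
  methods::new("StageSeries", years = as.integer(years), stages = stages,
               cutoffs = q, volumes = as.numeric(volumes))
}

#' Look up the stage of a year
#'
#' @param stageSeries a [StageSeries].
#' @param year integer year(s).
#' @return factor of stages (NA level dropped to error for unknown years).
#' @export
stageOf <- function(stageSeries, year) {
  i <- match(year, stageSeries@years)
  if (anyNA(i))
    stop("year(s) not in stage series: ",
         paste(year[is.na(i)], collapse = ", "))
  stageSeries@stages[i]
}

## Coded grid for target year index ti (1-based into series years):
## 0 = non-host, 1 = live host not recently attacked, 3 = attacked in
## year-1, 2 = attacked in year-2 (year-1 wins when both). With host
## mortality, cells attacked 3+ years before the target are dead: code 0.
.codedGrid <- function(series, ti, hostMortality = TRUE) {
  stopifnot(ti >= 3L)
  a1 <- series@attacks[, , ti - 1L]      # previous year
  a2 <- series@attacks[, , ti - 2L]
  g <- matrix(0L, nrow(series@host), ncol(series@host))
  host <- series@host == 1L
  if (hostMortality && ti > 3L) {
    older <- matrix(0L, nrow(g), ncol(g))
    for (k in seq_len(ti - 3L)) older <- older + series@attacks[, , k]
    live <- host & older == 0L
  } else live <- host
  g[live] <- 1L
  g[a2 == 1L] <- 2L
  g[a1 == 1L] <- 3L
  g
}

## Which cells are eligible focal cells for target year index ti:
## live hosts (never attacked before the target year when hostMortality).
.eligibleMask <- function(series, ti, hostMortality = TRUE) {
  host <- series@host == 1L
  if (!hostMortality) return(host)
  prior <- matrix(0L, nrow(series@host), ncol(series@host))
  for (k in seq_len(ti - 1L)) prior <- prior + series@attacks[, , k]
  host & prior == 0L
}

#' Encode the 19 x 19 neighborhood of a focal cell
#'
#' Cells are coded 0 = non-host, 1 = host not recently attacked,
#' 2 = attacked two years before the target year, 3 = attacked the year
#' before (the more recent attack wins); cells outside the landscape are 0.
#' With `hostMortality`, hosts killed three or more years earlier code 0.
#'
#' @param series a [LandscapeSeries].
#' @param row,col focal cell (1-based).
#' @param year target year; must have two predecessors in the series.
#' @param hostMortality treat previously attacked cells as dead (default).
#' @return 19 x 19 integer matrix centered on the focal cell.
#' @export
encodeWindow <- function(series, row, col, year, hostMortality = TRUE) {
  d <- dim(series@host)
  if (row < 1L || row > d[1] || col < 1L || col > d[2])
    stop("bounds error: focal cell (", row, ", ", col, ") outside the ",
         d[1], "x", d[2], " landscape")
  ti <- match(year, series@years)
  if (is.na(ti) || ti < 3L)
    stop("year ", year, " does not have two preceding years in the series")
  g <- .codedGrid(series, ti, hostMortality)
  gp <- matrix(0L, d[1] + 2L * .WRADIUS, d[2] + 2L * .WRADIUS)
  gp[.WRADIUS + seq_len(d[1]), .WRADIUS + seq_len(d[2])] <- g
  gp[row + seq_len(.WINDOW) - 1L, col + seq_len(.WINDOW) - 1L]
}

#' Build the example set from a landscape series
#'
#' Produces one example per eligible focal cell and target year. Target
#' years are all years with two predecessors in the series; eligible cells
#' are host cells, minus (by default) cells killed by a previous attack.
#' Labels come from the target-year attack map; each example carries the
#' focal cell's long-term mean temperature and the regional outbreak stage
#' of the year preceding the target year.
#'
#' @param series a validated [LandscapeSeries].
#' @param stages a [StageSeries] covering all years preceding target years;
#'   default fits terciles on the series' own regional volumes.
#' @param hostMortality drop previously attacked cells from the focal set
#'   (biologically standard: beetle-killed trees are no longer hosts).
#' @return a [BeetleExampleSet].
#' @examples
#' ls <- makeFixture("tiny", seed = 7)$series
#' es <- buildExamples(ls)
#' classCounts(es)
#' @export
buildExamples <- function(series, stages = classifyOutbreakStages(series),
                          hostMortality = TRUE) {
  d <- dim(series@host)
  tis <- seq_along(series@years)[-(1:2)]
  if (!length(tis)) stop("series has no year with two predecessors")
  off <- as.vector(outer(seq_len(.WINDOW) - 1L,
                         (seq_len(.WINDOW) - 1L) * (d[1] + 2L * .WRADIUS),
                         "+"))
  blocks <- vector("list", length(tis))
  meta <- vector("list", length(tis))
  for (j in seq_along(tis)) {
    ti <- tis[j]
    elig <- which(.eligibleMask(series, ti, hostMortality))
    if (!length(elig)) next
    g <- .codedGrid(series, ti, hostMortality)
    gp <- matrix(0L, d[1] + 2L * .WRADIUS, d[2] + 2L * .WRADIUS)
    gp[.WRADIUS + seq_len(d[1]), .WRADIUS + seq_len(d[2])] <- g
    rc <- arrayInd(elig, d)
    # top-left corner of each window in the padded grid, column-major index
    base <- rc[, 1] + (rc[, 2] - 1L) * (d[1] + 2L * .WRADIUS)
    win <- matrix(gp[outer(base, off, "+")], nrow = length(elig))
    blocks[[j]] <- t(win)
    meta[[j]] <- data.frame(
      label = series@attacks[, , ti][elig],
      year = series@years[ti], row = rc[, 1], col = rc[, 2],
      temperature = series@temperature[elig])
  }
  keep <- !vapply(blocks, is.null, TRUE)
  if (!any(keep)) stop("empty example set: no eligible focal cells")
  W <- do.call(cbind, blocks[keep])
  md <- do.call(rbind, meta[keep])
  md$stage <- stageOf(stages, md$year - 1L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(window = W),
    colData = S4Vectors::DataFrame(md))
  S4Vectors::metadata(se) <- list(
    cellSize = series@cellSize,
    gridDim = d,
    stageCutoffs = stages@cutoffs,
    hostMortality = hostMortality)
  methods::new("BeetleExampleSet", se)
}

#' Split an example set by held-out target years
#'
#' The test set contains exactly the examples whose target year is a
#' holdout year; train and test are disjoint and exhaustive. This is the
#' forward-prediction style design (one held-out year per outbreak stage
#' in the study: a background, a gradation and a culmination year).
#'
#' @param examples a [BeetleExampleSet].
#' @param holdoutYears integer years to hold out.
#' @return list with elements `train` and `test`.
#' @export
splitByYears <- function(examples, holdoutYears) {
  yrs <- unique(examples$year)
  miss <- setdiff(holdoutYears, yrs)
  if (length(miss))
    stop("holdout year(s) not in the example set: ",
         paste(miss, collapse = ", "))
  inTest <- examples$year %in% holdoutYears
  if (all(inTest)) stop("holdout covers every target year; train set empty")
  list(train = examples[, !inTest], test = examples[, inTest])
}

#' Random train/test split
#'
#' Holds out `round(fraction * n)` examples chosen uniformly at random
#' (no stratification), reproducibly for a fixed seed.
#'
#' @param examples a [BeetleExampleSet].
#' @param fraction test fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`.
#' @export
splitRandom <- function(examples, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- ncol(examples)
  nTest <- round(fraction * n)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  testIdx <- sort(sample.int(n, nTest))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  inTest <- logical(n); inTest[testIdx] <- TRUE
  list(train = examples[, !inTest], test = examples[, inTest])
}
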