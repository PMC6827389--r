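#' @include AllClasses.R
NULL

## Linear ("same") 2-D convolution via FFT with zero padding; odd kernels.
.conv2same <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m); kr <- nrow(kern); kc <- ncol(kern)
  NR <- nr + kr - 1L; NC <- nc + kc - 1L
  M <- matrix(0, NR, NC); M[seq_len(nr), seq_len(nc)] <- m
  K <- matrix(0, NR, NC); K[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(M) * stats::fft(K), inverse = TRUE)) /
    (NR * NC)
  full[(kr - 1L) %/% 2L + seq_len(nr), (kc - 1L) %/% 2L + seq_len(nc)]
}

.gaussKernel <- function(sd) {
  r <- max(1L, ceiling(3 * sd))
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- exp(-d / (2 * sd^2))
  k / sum(k)
}

## Exponential dispersal kernel, e-folding `scale` cells, truncated at
## `radius` cells (9 = 270 m at the 30 m grain). The center weight is 1 and
## the kernel is NOT normalized: the convolution yields a distance-
## discounted count of attacked neighbors, so `wRecent` reads as the logit
## effect of one adjacent attacked cell — the natural scale for the strong
## local spot-growth contagion of bark beetle systems. The focal cell's own
## weight is zeroed (self-attack state is host status, not pressure).
.dispersalKernel <- function(radius, scale) {
  d <- sqrt(outer((-radius:radius)^2, (-radius:radius)^2, "+"))
  k <- exp(-(d - 1) / scale)
  k[d > radius] <- 0
  k[radius + 1L, radius + 1L] <- 0
  k / k[radius + 1L, radius]    # weight 1 at distance 1
}

.subseed <- function(seed, k) as.integer(seed) + k * 1009L

#' Construct a simulation configuration
#'
#' Defaults define the reference synthetic landscape: 100 x 100 cells,
#' 14 years, ~60% spatially autocorrelated host cover, a 4.5-8.5 degC
#' north-south temperature gradient, contagious attacks with two-year
#' memory through an exponential dispersal kernel truncated at 9 cells
#' (270 m), and a two-peak regional forcing producing two outbreak waves.
#' The attack-rate parameters are calibrated so that ~3.5% of eligible
#' cell-years are attacked, matching the severe class imbalance of real
#' survey data.
#'
#' @param nRows,nCols,nYears grid and series size.
#' @param hostFraction,hostSmoothingScale host-map share and patch scale.
#' @param tempRange,tempNoiseSd temperature gradient endpoints and noise.
#' @param baselineLogit attack-logit intercept.
#' @param wRecent,wOlder logit effect per distance-discounted attacked
#'   neighbor (kernel weight 1 at distance 1) one / two years earlier.
#' @param wTemp effect per degC of temperature anomaly.
#' @param kernelRadius,kernelScale dispersal kernel truncation / e-folding
#'   distance in cells.
#' @param forcing per-year additive logit; NULL selects the default
#'   two-peak wave profile.
#' @param killHosts attacked cells leave the host pool (no re-attack).
#' @param volumePerCell,volumeNoiseSd disturbed-volume proxy (m3 per
#'   attacked cell) and its lognormal observation noise.
#' @param startYear first calendar year label.
#' @param seed root seed; host map, temperature, attacks and volume noise
#'   draw from derived substreams.
#' @return a validated [SimulationConfig].
#' @export
simulationConfig <- function(nRows = 100L, nCols = 100L, nYears = 14L,
                             hostFraction = 0.6, hostSmoothingScale = 3,
                             tempRange = c(4.5, 8.5), tempNoiseSd = 0.3,
                             baselineLogit = -7.8, wRecent = 1.7, wOlder = 0.55,
                             wTemp = 0.25, kernelRadius = 9L,
                             kernelScale = 1.2, forcing = NULL,
                             killHosts = TRUE, volumePerCell = 36,
                             volumeNoiseSd = 0.1, startYear = 2000L,
                             seed = 1L) {
  if (is.null(forcing)) forcing <- .defaultForcing(nYears)
  methods::new("SimulationConfig",
               nRows = as.integer(nRows), nCols = as.integer(nCols),
               nYears = as.integer(nYears), hostFraction = hostFraction,
               hostSmoothingScale = hostSmoothingScale,
               tempRange = tempRange, tempNoiseSd = tempNoiseSd,
               baselineLogit = baselineLogit, wRecent = wRecent,
               wOlder = wOlder, wTemp = wTemp,
               kernelRadius = as.integer(kernelRadius),
               kernelScale = kernelScale, forcing = forcing,
               killHosts = killHosts, volumePerCell = volumePerCell,
               volumeNoiseSd = volumeNoiseSd,
               startYear = as.integer(startYear), seed = as.integer(seed))
}

## Two Gaussian bumps over the series: an early and a later, stronger wave.
.defaultForcing <- function(nYears) {
  t <- seq_len(nYears)
  p1 <- round(nYears * 0.3); p2 <- round(nYears * 0.75)
  3.55 * exp(-0.5 * ((t - p1) / 1.6)^2) + 3.95 * exp(-0.5 * ((t - p2) / 1.8)^2)
}

#' Generate a spatially autocorrelated binary host map
#'
#' Gaussian-smoothed white noise thresholded at the quantile that yields
#' the target host fraction, so the realized fraction matches the target
#' to within ties.
#'
#' @param config a [SimulationConfig].
#' @return integer matrix in \{0,1\}.
#' @export
generateHostMap <- function(config) {
  set.seed(.subseed(config@seed, 1L))
  z <- matrix(stats::rnorm(config@nRows * config@nCols),
              config@nRows, config@nCols)
  sm <- .conv2same(z, .gaussKernel(config@hostSmoothingScale))
  th <- stats::quantile(sm, 1 - config@hostFraction, names = FALSE)
  matrix(as.integer(sm >= th), config@nRows, config@nCols)
}

.generateTemperature <- function(config, host) {
  set.seed(.subseed(config@seed, 2L))
  grad <- seq(config@tempRange[1], config@tempRange[2],
              length.out = config@nRows)
  matrix(grad, config@nRows, config@nCols) +
    matrix(stats::rnorm(config@nRows * config@nCols, 0, config@tempNoiseSd),
           config@nRows, config@nCols)
}

#' Simulate a contagious outbreak landscape series
#'
#' For every year from the third onward (the first two years are seeded
#' from baseline + forcing alone, having no attack memory), each eligible
#' host cell is attacked with probability
#' `plogis(baselineLogit + wRecent*K1 + wOlder*K2 + wTemp*(T - mean T) +
#' forcing[year])`, where K1 and K2 are distance-discounted counts of
#' cells attacked one and two years earlier (dispersal-kernel weighted,
#' weight 1 for an adjacent cell). With
#' `killHosts`, attacked cells leave the host pool, so no cell is attacked
#' twice. The regional disturbed-volume series is the annual attacked-cell
#' count times `volumePerCell`, under multiplicative lognormal observation
#' noise, so outbreak-stage classification is exercised end to end.
#'
#' @param config a [SimulationConfig].
#' @return a validated [LandscapeSeries].
#' @examples
#' ls <- simulateOutbreak(simulationConfig(nRows = 30, nCols = 30,
#'                                         nYears = 6, seed = 3))
#' apply(attackMaps(ls), 3, sum)   # annual attacked-cell counts
#' @export
simulateOutbreak <- function(config) {
  methods::validObject(config)
  host <- generateHostMap(config)
  if (!any(host == 1L)) stop("degenerate host map: no host cells")
  temp <- .generateTemperature(config, host)
  kern <- .dispersalKernel(config@kernelRadius, config@kernelScale)
  nR <- config@nRows; nC <- config@nCols; nY <- config@nYears
  tAnom <- temp - mean(temp[host == 1L])
  attacks <- array(0L, c(nR, nC, nY))
  alive <- host == 1L
  set.seed(.subseed(config@seed, 3L))
  for (y in seq_len(nY)) {
    if (y <= 2L) {
      K1 <- K2 <- matrix(0, nR, nC)
    } else {
      K1 <- .conv2same(attacks[, , y - 1L], kern)
      K2 <- .conv2same(attacks[, , y - 2L], kern)
    }
    logit <- config@baselineLogit + config@wRecent * K1 +
      config@wOlder * K2 + config@wTemp * tAnom + config@forcing[y]
    p <- stats::plogis(logit)
    draw <- matrix(stats::runif(nR * nC), nR, nC) < p
    hit <- draw & alive
    attacks[, , y][hit] <- 1L
    if (config@killHosts) alive <- alive & !hit
  }
  set.seed(.subseed(config@seed, 4L))
  counts <- apply(attacks, 3, sum)
  vol <- counts * config@volumePerCell *
    exp(stats::rnorm(nY, 0, config@volumeNoiseSd))
  years <- config@startYear + seq_len(nY) - 1L
  methods::new("LandscapeSeries", host = host, attacks = attacks,
               temperature = temp,
               regionalVolume = stats::setNames(vol, years),
               years = years, cellSize = 30,
               geo = list(xllcorner = 0, yllcorner = 0))
}

#' Named fixture landscapes for testing and calibration
#'
#' Presets:
#' * `"tiny"` — 30 x 30 x 5 years, default process; quick unit tests.
#' * `"separable"` — labels a deterministic function of the window: a host
#'   cell is attacked exactly when its left neighbor was attacked the year
#'   before, so the label equals `window code at center-left == 3`; build
#'   examples with `hostMortality = FALSE`. For train-to-perfection tests.
#' * `"two_wave"` — the 100 x 100 x 14 year reference landscape with two
#'   forced outbreak waves and ~3.5% attacked cell-years.
#' * `"null"` — no contagion, no temperature effect, flat forcing:
#'   attacks are iid at the target prevalence (negative control; no model
#'   should find skill here).
#'
#' @param preset one of `"tiny"`, `"separable"`, `"two_wave"`, `"null"`.
#' @param seed integer seed.
#' @return list with `series` (a [LandscapeSeries]) and `expected`
#'   (preset-specific reference summaries).
#' @export
makeFixture <- function(preset = c("tiny", "separable", "two_wave", "null"),
                        seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    cfg <- simulationConfig(nRows = 30L, nCols = 30L, nYears = 5L, seed = seed)
    list(series = simulateOutbreak(cfg), config = cfg,
         expected = list(dim = c(30L, 30L), nYears = 5L))
  } else if (preset == "two_wave") {
    cfg <- simulationConfig(seed = seed)
    series <- simulateOutbreak(cfg)
    list(series = series, config = cfg,
         expected = list(dim = c(100L, 100L), nYears = 14L,
                         targetPrevalence = 0.035,
                         forcingPeaks = c(round(14 * 0.3), round(14 * 0.75))))
  } else if (preset == "null") {
    cfg <- simulationConfig(wRecent = 0, wOlder = 0, wTemp = 0,
                            baselineLogit = stats::qlogis(0.035),
                            forcing = rep(0, 14), killHosts = FALSE,
                            seed = seed)
    list(series = simulateOutbreak(cfg), config = cfg,
         expected = list(prevalence = 0.035))
  } else {
    # separable: deterministic left-neighbor propagation
    cfg <- simulationConfig(nRows = 40L, nCols = 40L, nYears = 6L,
                            killHosts = FALSE, seed = seed)
    host <- generateHostMap(cfg)
    temp <- .generateTemperature(cfg, host)
    nY <- 6L
    attacks <- array(0L, c(40L, 40L, nY))
    set.seed(.subseed(cfg@seed, 3L))
    attacks[, , 1L] <- host *
      matrix(as.integer(stats::runif(1600) < 0.1), 40L, 40L)
    for (y in 2:nY) {
      left <- cbind(0L, attacks[, -40L, y - 1L])
      attacks[, , y] <- host * left
    }
    counts <- apply(attacks, 3, sum)
    years <- cfg@startYear + seq_len(nY) - 1L
    series <- methods::new("LandscapeSeries", host = host, attacks = attacks,
                           temperature = temp,
                           regionalVolume = stats::setNames(
                             counts * cfg@volumePerCell + 1, years),
                           years = years, cellSize = 30,
                           geo = list(xllcorner = 0, yllcorner = 0))
    # center-left window cell, column-major index in the flattened window
    idx <- (.WRADIUS + 1L) + (.WRADIUS - 1L) * .WINDOW
    list(series = series, config = cfg,
         expected = list(ruleIndex = idx, hostMortality = FALSE))
  }
}
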