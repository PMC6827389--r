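#' @include AllClasses.R
NULL

## ESRI ASCII grid: text raster with a small header, rows top to bottom.
## Values are written with "%.17g" so doubles round-trip bit-exactly.
.readAsc <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("empty ASCII grid: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) >= 2L && grepl("^[A-Za-z]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (is.null(nr) || is.null(nc))
    stop("ASCII grid header lacks nrows/ncols: ", path)
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid has ", length(vals), " values, expected ", nr * nc,
         ": ", path)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  # file rows are grid rows top->bottom; fill matrix by row
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  attr(m, "geo") <- hdr[intersect(names(hdr),
                                  c("xllcorner", "yllcorner", "cellsize"))]
  m
}

.writeAsc <- function(m, path, geo = list(), nodata = -9999) {
  nr <- nrow(m); nc <- ncol(m)
  xl <- if (!is.null(geo$xllcorner)) geo$xllcorner else 0
  yl <- if (!is.null(geo$yllcorner)) geo$yllcorner else 0
  cs <- if (!is.null(geo$cellsize)) geo$cellsize else 30
  vals <- t(m)                         # row-major order for writing
  vals[is.na(vals)] <- nodata
  lines <- c(sprintf("ncols %d", nc),
             sprintf("nrows %d", nr),
             sprintf("xllcorner %.17g", xl),
             sprintf("yllcorner %.17g", yl),
             sprintf("cellsize %.17g", cs),
             sprintf("NODATA_value %.17g", nodata),
             vapply(seq_len(nr), function(i)
               paste(sprintf("%.17g", vals[, i]), collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) {
    .readAsc(path)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(x)) == 3L) x <- x[, , 1]   # single band expected
    x
  } else stop("unsupported raster format: ", path)
}

#' Read and validate a landscape raster stack
#'
#' Reads the potential-host map, one binary attack map per year, the
#' long-term mean annual temperature surface and the annual regional
#' disturbed-timber volume table, checks that all grids align, and returns
#' a validated [LandscapeSeries]. ESRI ASCII grids (`.asc`) are the primary
#' dialect; plain single-band TIFF (`.tif`) is also read. NODATA cells in
#' the host map become non-host; NODATA in an attack map becomes 0. Attack
#' values other than 0/1 are an error (the offending cell is reported), as
#' are grid-shape mismatches, gaps in the attack-year sequence, and volume
#' tables that do not cover the attack years.
#'
#' @param hostPath,temperaturePath paths to single-band rasters.
#' @param attackPaths character vector of per-year attack rasters, one per
#'   calendar year, in year order.
#' @param volumePath CSV with columns `year` and `volume`.
#' @param years integer years of `attackPaths`; if NULL, parsed as the first
#'   4-digit run in each file name.
#' @param cellSize cell edge in metres; if NULL, taken from the ASCII-grid
#'   header (default 30 when absent).
#' @return a [LandscapeSeries].
#' @examples
#' ls <- simulateOutbreak(simulationConfig(nRows = 20, nCols = 20,
#'                                         nYears = 5, seed = 1))
#' d <- tempfile(); dir.create(d)
#' writeLandscape(ls, d)
#' ls2 <- readLandscape(file.path(d, "host.asc"),
#'                      list.files(d, "attack_", full.names = TRUE),
#'                      file.path(d, "temperature.asc"),
#'                      file.path(d, "volumes.csv"))
#' @export
readLandscape <- function(hostPath, attackPaths, temperaturePath, volumePath,
                          years = NULL, cellSize = NULL) {
  host <- .readRaster(hostPath)
  geo <- attr(host, "geo")
  if (is.null(cellSize))
    cellSize <- if (!is.null(geo$cellsize)) geo$cellsize else 30
  temp <- .readRaster(temperaturePath)
  attr(temp, "geo") <- NULL
  if (!identical(dim(temp), dim(host)))
    stop("alignment error: temperature grid is ",
         paste(dim(temp), collapse = "x"), ", host grid is ",
         paste(dim(host), collapse = "x"))
  if (is.null(years)) {
    yr <- regmatches(basename(attackPaths),
                     regexpr("[0-9]{4}", basename(attackPaths)))
    if (length(yr) != length(attackPaths))
      stop("could not parse a 4-digit year from every attack file name; ",
           "pass `years` explicitly")
    years <- as.integer(yr)
  }
  o <- order(years)
  years <- years[o]; attackPaths <- attackPaths[o]
  if (length(years) > 1L && !all(diff(years) == 1L))
    stop("sequence error: attack years are not consecutive (",
         paste(years, collapse = ", "), ")")
  atk <- array(0L, c(dim(host), length(years)))
  for (i in seq_along(attackPaths)) {
    a <- .readRaster(attackPaths[i])
    if (!identical(dim(a), dim(host)))
      stop("alignment error: attack grid ", basename(attackPaths[i]),
           " is ", paste(dim(a), collapse = "x"), ", host grid is ",
           paste(dim(host), collapse = "x"))
    a[is.na(a)] <- 0
    bad <- which(!(a %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(a))
      stop("attack map ", basename(attackPaths[i]), " is not binary: value ",
           format(a[bad[1]]), " at (row ", rc[1], ", col ", rc[2], ")")
    }
    atk[, , i] <- as.integer(a)
  }
  vt <- utils::read.csv(volumePath)
  if (!all(c("year", "volume") %in% names(vt)))
    stop("volume table must have columns 'year' and 'volume'")
  miss <- setdiff(years, vt$year)
  if (length(miss))
    stop("coverage error: volume table missing year(s) ",
         paste(miss, collapse = ", "))
  vol <- stats::setNames(as.numeric(vt$volume), as.character(vt$year))
  hostI <- matrix(0L, nrow(host), ncol(host))
  hostI[!is.na(host) & host == 1] <- 1L
  methods::new("LandscapeSeries", host = hostI, attacks = atk,
               temperature = temp, regionalVolume = vol,
               years = as.integer(years), cellSize = cellSize,
               geo = if (is.null(geo)) list() else geo)
}

#' Write a landscape series to a directory
#'
#' Writes `host.asc`, `temperature.asc`, one `attack_<year>.asc` per year,
#' and `volumes.csv`, in exactly the layout [readLandscape()] reads.
#'
#' @param series a [LandscapeSeries].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeLandscape <- function(series, dir) {
  stopifnot(methods::is(series, "LandscapeSeries"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geo <- series@geo
  geo$cellsize <- series@cellSize
  .writeAsc(series@host, file.path(dir, "host.asc"), geo)
  .writeAsc(series@temperature, file.path(dir, "temperature.asc"), geo)
  for (i in seq_along(series@years))
    .writeAsc(series@attacks[, , i],
              file.path(dir, sprintf("attack_%d.asc", series@years[i])), geo)
  utils::write.csv(
    data.frame(year = as.integer(names(series@regionalVolume)),
               volume = unname(series@regionalVolume)),
    file.path(dir, "volumes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a probability surface
#'
#' Probability maps carry one attack probability per scored cell and NA
#' elsewhere (non-host or otherwise unscored cells), stored as an ESRI
#' ASCII grid with NODATA sentinel (or 32-bit float TIFF for `.tif`).
#' ASCII grids round-trip bit-exactly through [readProbabilityMap()].
#'
#' @param grid numeric matrix with finite values in [0,1] or NA.
#' @param path output path (`.asc` or `.tif`).
#' @param geo optional georeferencing list (xllcorner, yllcorner, cellsize).
#' @return `writeProbabilityMap`: the path, invisibly;
#'   `readProbabilityMap`: a numeric matrix with NA sentinels.
#' @export
writeProbabilityMap <- function(grid, path, geo = list()) {
  v <- grid[!is.na(grid)]
  if (any(!is.finite(v) | v < 0 | v > 1))
    stop("range error: probability values must be finite and in [0,1]")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    g <- grid
    g[is.na(g)] <- 0          # TIFF has no NODATA; ASCII is the lossless path
    tiff::writeTIFF(g, path, bits.per.sample = 32L)
  } else {
    .writeAsc(grid, path, geo)
  }
  invisible(path)
}

#' @rdname writeProbabilityMap
#' @export
readProbabilityMap <- function(path) {
  m <- .readRaster(path)
  attr(m, "geo") <- NULL
  m
}
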