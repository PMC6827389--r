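# Hand-built miniature landscape: 12 x 12 cells, 4 years. Host everywhere
# except a non-host block in the top-left corner; attacks placed by hand so
# window codes are predictable.
handLandscape <- function() {
  host <- matrix(1L, 12, 12)
  host[1:3, 1:3] <- 0L
  attacks <- array(0L, c(12, 12, 4))
  attacks[6, 5, 2] <- 1L   # year 2: left neighbor of (6,6)
  attacks[9, 9, 1] <- 1L   # year 1
  attacks[9, 10, 3] <- 1L  # year 3
  temp <- matrix(seq(5, 8, length.out = 12), 12, 12)
  methods::new("LandscapeSeries",
               host = host, attacks = attacks, temperature = temp,
               regionalVolume = stats::setNames(c(10, 40, 20, 80), 2001:2004),
               years = 2001:2004, cellSize = 30,
               geo = list(xllcorner = 0, yllcorner = 0))
}

# Write a matrix as an ESRI ASCII grid (duplicates none of the package
# internals on purpose: header written literally).
writeAscFixture <- function(m, path, nodata = -9999) {
  lines <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
             "xllcorner 0", "yllcorner 0", "cellsize 30",
             paste("NODATA_value", nodata),
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
  path
}

# Brute-force confusion tally by explicit looping (independent oracle).
bruteConfusion <- function(labels, preds) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1L
    else if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1L
    else if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Brute-force F1 over candidate thresholds (independent oracle).
bruteBestF1 <- function(probabilities, labels, thresholds) {
  best <- -1
  for (t in thresholds) {
    pred <- as.integer(probabilities >= t)
    tp <- sum(labels == 1 & pred == 1)
    fp <- sum(labels == 0 & pred == 1)
    fn <- sum(labels == 1 & pred == 0)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) best <- f1
  }
  best
}

# Step-by-step Gleichlaeufigkeit (independent of the vectorized version).
bruteGleich <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    gx <- if (x[i + 1] - x[i] > 0) 0.5 else if (x[i + 1] - x[i] < 0) -0.5 else 0
    gy <- if (y[i + 1] - y[i] > 0) 0.5 else if (y[i + 1] - y[i] < 0) -0.5 else 0
    s <- s + abs(gx + gy)
  }
  s / (length(x) - 1)
}
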