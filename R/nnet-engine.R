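#' @include AllClasses.R
#' @importFrom Matrix sparseMatrix
NULL

## ---------------------------------------------------------------------------
## Minimal deterministic neural-network engine.
##
## Layout conventions:
##   * conv activations: array [batch, H, W, channels]
##   * dense activations: matrix [batch, units]
##   * conv weights: matrix [k*k*Cin, Cout] with kernel index fastest
##     (dh, then dw, then input channel), biases length Cout
##   * convolutions are "same"-padded (asymmetric ceil pad right/bottom)
##     with configurable stride; im2col gather + one matrix product per
##     layer; the input gradient is recovered through a precomputed sparse
##     scatter (col2im) matrix.
## Everything runs on base R doubles + BLAS, seeded through the R RNG, so
## fixed seed => bit-identical training in a single-threaded BLAS.
## ---------------------------------------------------------------------------

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.convGeom <- function(H, W, k, s) {
  Ho <- as.integer(ceiling(H / s)); Wo <- as.integer(ceiling(W / s))
  padH <- max((Ho - 1L) * s + k - H, 0L); padW <- max((Wo - 1L) * s + k - W, 0L)
  Hp <- H + padH; Wp <- W + padW
  top <- padH %/% 2L; left <- padW %/% 2L
  jOff <- rep(seq_len(k) - 1L, k) + rep(seq_len(k) - 1L, each = k) * Hp
  ho <- rep(seq_len(Ho), Wo); wo <- rep(seq_len(Wo), each = Ho)
  oBase <- ((ho - 1L) * s + 1L) + ((wo - 1L) * s) * Hp
  # output position fastest, kernel index slowest: the gathered block can be
  # reshaped straight to [B*O, J*C] without a transpose
  posidx <- as.vector(outer(oBase, jOff, "+"))
  S <- Matrix::sparseMatrix(i = posidx, j = seq_along(posidx), x = 1,
                            dims = c(Hp * Wp, length(posidx)))
  list(H = H, W = W, k = k, s = s, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
       top = top, left = left, posidx = posidx, S = S, J = k * k)
}

.padInput <- function(x, g) {
  d <- dim(x)
  if (g$Hp == d[2] && g$Wp == d[3]) return(x)
  xp <- array(0, c(d[1], g$Hp, g$Wp, d[4]))
  xp[, g$top + seq_len(d[2]), g$left + seq_len(d[3]), ] <- x
  xp
}

## im2col: [B,H,W,Cin] -> patch matrix [B*Ho*Wo, J*Cin].
## posidx is ordered output-position fastest, so the gathered [B, O*J, Cin]
## block already has dimension order (B, O, J, Cin) and reshapes in place.
.im2col <- function(x, g) {
  B <- dim(x)[1]; Cin <- dim(x)[4]
  xp <- .padInput(x, g)
  dim(xp) <- c(B, g$Hp * g$Wp, Cin)
  P <- xp[, g$posidx, , drop = FALSE]
  dim(P) <- c(B * g$Ho * g$Wo, g$J * Cin)
  P
}

## col2im (scatter-add): patch-gradient [B*Ho*Wo, J*Cin] -> [B,H,W,Cin]
.col2im <- function(dP, g, B, Cin) {
  dim(dP) <- c(B, g$Ho * g$Wo, g$J, Cin)
  dP <- aperm(dP, c(2, 3, 1, 4))              # [O, J, B, Cin] = posidx order
  dim(dP) <- c(g$Ho * g$Wo * g$J, B * Cin)
  dXp <- as.matrix(g$S %*% dP)                 # [Hp*Wp, B*Cin]
  dim(dXp) <- c(g$Hp * g$Wp, B, Cin)
  dXp <- aperm(dXp, c(2, 1, 3))
  dim(dXp) <- c(B, g$Hp, g$Wp, Cin)
  dXp[, g$top + seq_len(g$H), g$left + seq_len(g$W), , drop = FALSE]
}

.bnForward <- function(layer, Z, training) {
  n <- nrow(Z)
  if (training) {
    mu <- .colMeans(Z, n, ncol(Z))
    v <- .colMeans(Z * Z, n, ncol(Z)) - mu * mu
    v[v < 0] <- 0
  } else {
    mu <- layer$rm; v <- layer$rv
  }
  istd <- 1 / sqrt(v + .BN_EPS)
  xhat <- (Z - rep(mu, each = n)) * rep(istd, each = n)
  out <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  list(out = out, xhat = xhat, istd = istd, mu = mu, v = v)
}

.bnBackward <- function(layer, cache, dOut) {
  n <- nrow(dOut); p <- ncol(dOut)
  dgamma <- .colSums(dOut * cache$xhat, n, p)
  dbeta <- .colSums(dOut, n, p)
  dxhat <- dOut * rep(layer$gamma, each = n)
  dZ <- rep(cache$istd, each = n) *
    (dxhat - rep(.colMeans(dxhat, n, p), each = n) -
       cache$xhat * rep(.colMeans(dxhat * cache$xhat, n, p), each = n))
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

.initLayers <- function(config, Cin, nAux) {
  layers <- list()
  H <- .WINDOW; W <- .WINDOW; C <- Cin
  k <- config@kernelSize
  for (i in seq_along(config@convChannels)) {
    g <- .convGeom(H, W, k, config@convStrides[i])
    Cout <- config@convChannels[i]
    fanIn <- k * k * C
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(stats::rnorm(fanIn * Cout, 0, sqrt(2 / fanIn)), fanIn, Cout),
      b = numeric(Cout), geom = g, bn = config@batchNorm,
      gamma = rep(1, Cout), beta = numeric(Cout),
      rm = numeric(Cout), rv = rep(1, Cout))
    H <- g$Ho; W <- g$Wo; C <- Cout
  }
  dIn <- H * W * C + nAux
  for (w in config@denseWidths) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(stats::rnorm(dIn * w, 0, sqrt(2 / dIn)), dIn, w),
      b = numeric(w), bn = config@batchNorm,
      gamma = rep(1, w), beta = numeric(w), rm = numeric(w), rv = rep(1, w),
      dropout = config@dropoutRate)
    dIn <- w
  }
  layers[[length(layers) + 1L]] <- list(
    type = "out",
    W = matrix(stats::rnorm(dIn * 2, 0, sqrt(1 / dIn)), dIn, 2),
    b = numeric(2))
  list(layers = layers, flatDim = c(H, W, C), nAux = nAux, Cin = Cin)
}

## Forward pass. Returns probs (n x 2, col 2 = positive class) and, when
## `keepCache`, per-layer caches for backprop. Running BN stats are updated
## in place on the returned net when training.
.netForward <- function(net, X, aux, training = FALSE, keepCache = FALSE) {
  layers <- net$layers
  caches <- vector("list", length(layers))
  A <- X
  for (li in seq_along(layers)) {
    layer <- layers[[li]]
    if (layer$type == "conv") {
      g <- layer$geom
      B <- dim(A)[1]; Cin <- dim(A)[4]
      P <- .im2col(A, g)
      Z <- P %*% layer$W
      Z <- Z + rep(layer$b, each = nrow(Z))
      bnCache <- NULL
      if (layer$bn) {
        bnCache <- .bnForward(layer, Z, training)
        if (training) {
          layers[[li]]$rm <- .BN_MOMENTUM * layer$rm + (1 - .BN_MOMENTUM) * bnCache$mu
          layers[[li]]$rv <- .BN_MOMENTUM * layer$rv + (1 - .BN_MOMENTUM) * bnCache$v
        }
        Z <- bnCache$out
      }
      mask <- Z > 0
      Z <- Z * mask
      if (keepCache)
        caches[[li]] <- list(P = P, bn = bnCache, mask = mask, B = B, Cin = Cin)
      dim(Z) <- c(B, g$Ho, g$Wo, ncol(layer$W))
      A <- Z
      if (li == length(layers) || layers[[li + 1L]]$type != "conv") {
        dim(A) <- c(B, prod(dim(A)[-1]))
        A <- cbind(A, aux)
      }
    } else if (layer$type == "dense") {
      Ain <- A
      Z <- A %*% layer$W
      Z <- Z + rep(layer$b, each = nrow(Z))
      bnCache <- NULL
      if (layer$bn) {
        bnCache <- .bnForward(layer, Z, training)
        if (training) {
          layers[[li]]$rm <- .BN_MOMENTUM * layer$rm + (1 - .BN_MOMENTUM) * bnCache$mu
          layers[[li]]$rv <- .BN_MOMENTUM * layer$rv + (1 - .BN_MOMENTUM) * bnCache$v
        }
        Z <- bnCache$out
      }
      mask <- Z > 0
      Z <- Z * mask
      drop <- NULL
      if (training && layer$dropout > 0) {
        drop <- matrix(stats::runif(length(Z)) >= layer$dropout,
                       nrow(Z), ncol(Z)) / (1 - layer$dropout)
        Z <- Z * drop
      }
      if (keepCache)
        caches[[li]] <- list(A = Ain, bn = bnCache, mask = mask, drop = drop)
      A <- Z
    } else {                                    # softmax output
      Z <- A %*% layer$W
      Z <- Z + rep(layer$b, each = nrow(Z))
      m <- pmax(Z[, 1], Z[, 2])
      e1 <- exp(Z[, 1] - m); e2 <- exp(Z[, 2] - m)
      probs <- cbind(e1, e2) / (e1 + e2)
      if (keepCache) caches[[li]] <- list(A = A)
    }
  }
  list(probs = probs, caches = caches, layers = layers)
}

## Backward pass from softmax cross entropy. y: 0/1 labels; w: example
## weights. Returns grads aligned with net$layers.
.netBackward <- function(net, fw, y, w) {
  layers <- net$layers
  caches <- fw$caches
  n <- length(y)
  grads <- vector("list", length(layers))
  Y <- cbind(1 - y, y)
  dZ <- (fw$probs - Y) * (w / sum(w))           # d loss / d logits
  li <- length(layers)
  layer <- layers[[li]]
  grads[[li]] <- list(W = crossprod(caches[[li]]$A, dZ), b = colSums(dZ))
  dA <- tcrossprod(dZ, layer$W)
  for (li in rev(seq_len(length(layers) - 1L))) {
    layer <- layers[[li]]
    cache <- caches[[li]]
    if (layer$type == "dense") {
      dZ <- dA
      if (!is.null(cache$drop)) dZ <- dZ * cache$drop
      dZ <- dZ * cache$mask
      g <- list()
      if (layer$bn) {
        bb <- .bnBackward(layer, cache$bn, dZ)
        dZ <- bb$dZ; g$gamma <- bb$dgamma; g$beta <- bb$dbeta
      }
      g$W <- crossprod(cache$A, dZ)
      g$b <- colSums(dZ)
      grads[[li]] <- g
      dA <- tcrossprod(dZ, layer$W)
    } else {                                    # conv
      geom <- layer$geom
      B <- cache$B
      Cout <- ncol(layer$W)
      # dA arrives flattened (with aux appended) right after the last conv
      if (is.matrix(dA)) {
        flat <- geom$Ho * geom$Wo * Cout
        dA <- dA[, seq_len(flat), drop = FALSE]
        dim(dA) <- c(B, geom$Ho, geom$Wo, Cout)
      }
      dZ <- dA
      dim(dZ) <- c(B * geom$Ho * geom$Wo, Cout)
      dZ <- dZ * cache$mask
      g <- list()
      if (layer$bn) {
        bb <- .bnBackward(layer, cache$bn, dZ)
        dZ <- bb$dZ; g$gamma <- bb$dgamma; g$beta <- bb$dbeta
      }
      g$W <- crossprod(cache$P, dZ)
      g$b <- colSums(dZ)
      grads[[li]] <- g
      if (li > 1L) {
        dP <- tcrossprod(dZ, layer$W)
        dA <- .col2im(dP, geom, B, cache$Cin)
      }
    }
  }
  grads
}

.initOptState <- function(layers) {
  lapply(layers, function(layer) {
    ps <- intersect(names(layer), c("W", "b", "gamma", "beta"))
    ps <- ps[!(ps %in% c("gamma", "beta")) | isTRUE(layer$bn)]
    st <- lapply(ps, function(p) {
      z <- layer[[p]]; z[] <- 0
      list(m = z, v = z)
    })
    names(st) <- ps
    st
  })
}

.applyGrads <- function(net, grads, opt, config, t) {
  lr <- config@learningRate; wd <- config@weightDecay
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (p in names(opt$state[[li]])) {
      if (is.null(g[[p]])) next
      gr <- g[[p]]
      if (p == "W" && wd > 0) gr <- gr + wd * net$layers[[li]][[p]]
      st <- opt$state[[li]][[p]]
      if (config@optimizer == "adam") {
        st$m <- 0.9 * st$m + 0.1 * gr
        st$v <- 0.999 * st$v + 0.001 * gr * gr
        mhat <- st$m / (1 - 0.9^t)
        vhat <- st$v / (1 - 0.999^t)
        net$layers[[li]][[p]] <- net$layers[[li]][[p]] -
          lr * mhat / (sqrt(vhat) + 1e-8)
      } else {                                   # SGD + momentum
        st$m <- 0.9 * st$m + gr
        net$layers[[li]][[p]] <- net$layers[[li]][[p]] - lr * st$m
      }
      opt$state[[li]][[p]] <- st
    }
  }
  list(net = net, opt = opt)
}

## Expand a batch of window-code rows into the input tensor.
.batchX <- function(codes, rows, mode) {
  B <- length(rows)
  cc <- codes[rows, , drop = FALSE]
  if (mode == "ordinal") {
    array(cc / 3, c(B, .WINDOW, .WINDOW, 1L))
  } else {
    x <- array(0, c(B, .WINDOW, .WINDOW, 3L))
    x[, , , 1L] <- array((cc >= 1L) * 1, c(B, .WINDOW, .WINDOW))
    x[, , , 2L] <- array((cc == 3L) * 1, c(B, .WINDOW, .WINDOW))
    x[, , , 3L] <- array((cc == 2L) * 1, c(B, .WINDOW, .WINDOW))
    x
  }
}

.enginePredict <- function(net, codes, aux, mode, chunk = 4096L) {
  n <- nrow(codes)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    rows <- i:j
    fw <- .netForward(net, .batchX(codes, rows, mode),
                      aux[rows, , drop = FALSE], training = FALSE)
    out[rows] <- fw$probs[, 2]
    i <- j + 1L
  }
  out
}

## Full training loop; returns best-epoch weights and the per-epoch history.
.engineTrain <- function(net, config, train, eval) {
  n <- length(train$y)
  w <- ifelse(train$y == 1L, config@classWeight, 1)
  opt <- list(state = .initOptState(net$layers))
  t <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     evalAccuracy = numeric())
  bestAcc <- -Inf
  bestLayers <- net$layers
  bs <- config@batchSize
  for (epoch in seq_len(config@epochs)) {
    perm <- sample.int(n)
    lossNum <- 0; lossDen <- 0
    for (start in seq(1L, n, by = bs)) {
      rows <- perm[start:min(start + bs - 1L, n)]
      if (length(rows) < 2L) next           # batch stats need >= 2 examples
      X <- .batchX(train$codes, rows, config@encodeMode)
      fw <- .netForward(net, X, train$aux[rows, , drop = FALSE],
                        training = TRUE, keepCache = TRUE)
      net$layers <- fw$layers               # running BN stats
      p <- fw$probs[cbind(seq_along(rows), train$y[rows] + 1L)]
      wi <- w[rows]
      lossNum <- lossNum + sum(-log(pmax(p, 1e-12)) * wi)
      lossDen <- lossDen + sum(wi)
      grads <- .netBackward(net, fw, train$y[rows], wi)
      t <- t + 1L
      up <- .applyGrads(net, grads, opt, config, t)
      net <- up$net; opt <- up$opt
    }
    pEval <- .enginePredict(net, eval$codes, eval$aux, config@encodeMode)
    acc <- mean((pEval >= 0.5) == (eval$y == 1L))
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = lossNum / lossDen,
                                   evalAccuracy = acc))
    if (acc > bestAcc) {
      bestAcc <- acc
      bestLayers <- net$layers
    }
  }
  net$layers <- bestLayers
  list(net = net, history = hist,
       selectedEpoch = which.max(hist$evalAccuracy))
}
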