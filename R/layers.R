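## Internal neural-network primitives. Tensors are R arrays (H, W, C, N).
## Convolutions run through the compiled im2col/GEMM kernels; batch
## normalization and the leaky ReLU are vectorized R. Each primitive has a
## matching backward so the full network is differentiable end to end.

convForward <- function(x, w, b, stride = 1L, pad = 1L) {
  .conv2dForward(x, w, b, as.integer(stride), as.integer(pad))
}

convBackward <- function(x, w, dy, stride = 1L, pad = 1L,
                         needDx = TRUE, needDw = TRUE) {
  .conv2dBackward(x, w, dy, as.integer(stride), as.integer(pad),
                  needDx, needDw)
}

## Batch normalization over (H, W, N) per channel. Works on the matrix
## reshape M (H*W*N x C) obtained by rotating the channel axis last.
.bnReshape <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

.bnRestore <- function(M, d) {
  aperm(array(M, dim = d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
}

bnForward <- function(x, gamma, beta, rm, rv, training,
                      eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  M <- .bnReshape(x)
  if (training) {
    m <- colMeans(M)
    v <- colMeans(M * M) - m * m   # biased, as is conventional in-batch
    rm <- (1 - momentum) * rm + momentum * m
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    m <- rm; v <- rv
  }
  ivstd <- 1 / sqrt(v + eps)
  Xhat <- sweep(sweep(M, 2L, m, "-"), 2L, ivstd, "*")
  Y <- sweep(sweep(Xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = .bnRestore(Y, d), rm = rm, rv = rv,
       cache = if (training) list(Xhat = Xhat, ivstd = ivstd,
                                  gamma = gamma, d = d) else NULL)
}

bnBackward <- function(dy, cache) {
  d <- cache$d
  dY <- .bnReshape(dy)
  Xhat <- cache$Xhat
  n <- nrow(dY)
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2L, cache$gamma, "*")
  sum1 <- colSums(dXhat)
  sum2 <- colSums(dXhat * Xhat)
  dM <- sweep(dXhat, 2L, sum1 / n, "-") -
    sweep(Xhat, 2L, sum2 / n, "*")
  dM <- sweep(dM, 2L, cache$ivstd, "*")
  list(dx = .bnRestore(dM, d), dgamma = dgamma, dbeta = dbeta)
}

lreluForward <- function(x, slope) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * y[neg]
  y
}

lreluBackward <- function(dy, x, slope) {
  dx <- dy
  neg <- x < 0
  dx[neg] <- slope * dx[neg]
  dx
}

## One conv + batch-norm + leaky-ReLU block. Parameter names inside the
## flat parameter list: "<blk>.w", "<blk>.b", "<blk>.g", "<blk>.be"; running
## stats in the state list: "<blk>.rm", "<blk>.rv".
cblForward <- function(x, par, st, blk, stride, pad, slope, training,
                       keepCache = TRUE) {
  z <- convForward(x, par[[paste0(blk, ".w")]], par[[paste0(blk, ".b")]],
                   stride, pad)
  bn <- bnForward(z, par[[paste0(blk, ".g")]], par[[paste0(blk, ".be")]],
                  st[[paste0(blk, ".rm")]], st[[paste0(blk, ".rv")]],
                  training)
  y <- lreluForward(bn$y, slope)
  st[[paste0(blk, ".rm")]] <- bn$rm
  st[[paste0(blk, ".rv")]] <- bn$rv
  cache <- if (keepCache) list(x = x, bn = bn$cache, act = bn$y) else NULL
  list(y = y, st = st, cache = cache)
}

cblBackward <- function(dy, cache, par, blk, stride, pad, slope,
                        needDx = TRUE) {
  dz <- lreluBackward(dy, cache$act, slope)
  bnb <- bnBackward(dz, cache$bn)
  cb <- convBackward(cache$x, par[[paste0(blk, ".w")]], bnb$dx,
                     stride, pad, needDx = needDx, needDw = TRUE)
  grads <- list(cb$dw, cb$db, bnb$dgamma, bnb$dbeta)
  names(grads) <- paste0(blk, c(".w", ".b", ".g", ".be"))
  list(dx = if (needDx) cb$dx else NULL, grads = grads)
}

## Parameter initialization: conv weights drawn from N(0, 0.01), biases 0,
## batch-norm scale 1 / shift 0, matching the training protocol.
initConvBlock <- function(par, st, blk, k, cin, cout, withBN = TRUE) {
  par[[paste0(blk, ".w")]] <- array(rnorm(k * k * cin * cout, 0, 0.01),
                                    dim = c(k, k, cin, cout))
  par[[paste0(blk, ".b")]] <- numeric(cout)
  if (withBN) {
    par[[paste0(blk, ".g")]] <- rep(1, cout)
    par[[paste0(blk, ".be")]] <- numeric(cout)
    st[[paste0(blk, ".rm")]] <- numeric(cout)
    st[[paste0(blk, ".rv")]] <- rep(1, cout)
  }
  list(par = par, st = st)
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## Adam with bias correction; operates on flat named lists of arrays.
adamInit <- function(par) {
  list(m = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adamStep <- function(par, grads, state, lr, betas = c(0.5, 0.999),
                     eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

accumulateGrads <- function(total, add) {
  for (nm in names(add))
    total[[nm]] <- if (is.null(total[[nm]])) add[[nm]] else total[[nm]] + add[[nm]]
  total
}
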