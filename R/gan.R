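## The adversarial pair. The generator is a deep convolutional framelet
## encoder-decoder: each contracting step applies two 3x3 conv + batch-norm
## + leaky-ReLU blocks and then a single-level Haar analysis; the LL band
## feeds the next step while LH/HL/HH skip to the matching expansive step,
## where they enter the Haar synthesis that performs the upsampling. The
## synthesized features are concatenated with the same-step contracting
## features, refined by two further conv blocks, and a final 1x1 convolution
## produces the grayscale output. The discriminator is four 4x4 stride-2
## conv + batch-norm + leaky-ReLU(0.2) layers followed by a 1x1 convolution
## yielding a one-channel spatial score map. Every convolution is zero
## padded.

#' Network architecture configuration
#'
#' @param depth number of contracting/expansive steps of the generator;
#'   inputs must be divisible by `2^depth`.
#' @param baseFeatures feature count at the first step; the default schedule
#'   doubles per step (`64, 128, ...`).
#' @param featureSchedule optional explicit per-step feature counts
#'   (length `depth`); overrides `baseFeatures`.
#' @param leakySlopeG,leakySlopeD negative slopes of the leaky ReLUs in
#'   generator and discriminator.
#' @param discLayers number of 4x4 stride-2 discriminator convolutions.
#' @param discBaseFeatures discriminator features at the first layer
#'   (doubling per layer).
#' @return A list of class-free configuration values consumed by
#'   [buildGenerator()] and [buildDiscriminator()].
#' @export
networkConfig <- function(depth = 4L, baseFeatures = 64L,
                          featureSchedule = NULL,
                          leakySlopeG = 0.2, leakySlopeD = 0.2,
                          discLayers = 4L, discBaseFeatures = 64L) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be a positive integer")
  if (is.null(featureSchedule))
    featureSchedule <- as.integer(baseFeatures * 2^(seq_len(depth) - 1L))
  featureSchedule <- as.integer(featureSchedule)
  if (length(featureSchedule) != depth)
    stop("featureSchedule must have one entry per contracting step")
  if (any(featureSchedule < 1L)) stop("feature counts must be positive")
  if (leakySlopeG <= 0 || leakySlopeG >= 1 || leakySlopeD <= 0 ||
      leakySlopeD >= 1)
    stop("leaky slopes must lie in (0, 1)")
  list(depth = depth, featureSchedule = featureSchedule,
       leakySlopeG = leakySlopeG, leakySlopeD = leakySlopeD,
       discLayers = as.integer(discLayers),
       discBaseFeatures = as.integer(discBaseFeatures))
}

## The fixed HU normalization window: the soft-tissue display window
## (width 250, level 125) widened to [-160, 400] HU and mapped linearly to
## [-1, 1]; exactly invertible.
huNormalization <- function() list(center = 120, scale = 280)

normalizeHU <- function(x, norm) (x - norm$center) / norm$scale
denormalizeHU <- function(x, norm) x * norm$scale + norm$center

#' Build the framelet generator G
#'
#' Allocates and initializes all generator parameters. Convolution weights
#' are drawn from a Gaussian with mean 0 and standard deviation 0.01,
#' biases start at zero, batch-normalization at scale 1 / shift 0.
#'
#' @param cfg a [networkConfig()] list.
#' @param seed integer seed; two builds with the same seed are identical.
#' @return A [GeneratorModel-class].
#' @export
buildGenerator <- function(cfg, seed = 1L) {
  set.seed(as.integer(seed))
  f <- cfg$featureSchedule
  d <- cfg$depth
  par <- list(); st <- list()
  cin <- 1L
  for (i in seq_len(d)) {
    r <- initConvBlock(par, st, sprintf("enc%d.ca", i), 3L, cin, f[i])
    r <- initConvBlock(r$par, r$st, sprintf("enc%d.cb", i), 3L, f[i], f[i])
    par <- r$par; st <- r$st
    cin <- f[i]
  }
  fb <- 2L * f[d]
  r <- initConvBlock(par, st, "bot.ca", 3L, f[d], fb)
  r <- initConvBlock(r$par, r$st, "bot.cb", 3L, fb, fb)
  par <- r$par; st <- r$st
  cprev <- fb
  for (i in rev(seq_len(d))) {
    r <- initConvBlock(par, st, sprintf("dec%d.cp", i), 3L, cprev, f[i])
    r <- initConvBlock(r$par, r$st, sprintf("dec%d.ca", i), 3L, 2L * f[i], f[i])
    r <- initConvBlock(r$par, r$st, sprintf("dec%d.cb", i), 3L, f[i], f[i])
    par <- r$par; st <- r$st
    cprev <- f[i]
  }
  r <- initConvBlock(par, st, "out", 1L, f[1L], 1L, withBN = FALSE)
  new("GeneratorModel", parameters = r$par, state = r$st, config = cfg,
      normalization = huNormalization())
}

#' Build the strided patch discriminator D
#'
#' @inheritParams buildGenerator
#' @return A [DiscriminatorModel-class]; on an input patch of side `L` the
#'   score map has side `L / 2^discLayers` (e.g. 8x8 for a 128 patch).
#' @export
buildDiscriminator <- function(cfg, seed = 1L) {
  set.seed(as.integer(seed))
  nl <- cfg$discLayers
  g <- as.integer(cfg$discBaseFeatures * 2^(seq_len(nl) - 1L))
  par <- list(); st <- list()
  cin <- 1L
  for (j in seq_len(nl)) {
    r <- initConvBlock(par, st, sprintf("d%d", j), 4L, cin, g[j])
    par <- r$par; st <- r$st
    cin <- g[j]
  }
  r <- initConvBlock(par, st, "dout", 1L, cin, 1L, withBN = FALSE)
  new("DiscriminatorModel", parameters = r$par, state = r$st, config = cfg)
}

#' An identity generator
#'
#' A degenerate [GeneratorModel-class] whose forward pass returns its input
#' unchanged. Used to verify that normalization, patch extraction and
#' overlap-averaged reassembly compose to a lossless round trip.
#'
#' @return A [GeneratorModel-class] flagged as the identity map.
#' @export
identityGenerator <- function() {
  cfg <- networkConfig(depth = 1L, baseFeatures = 1L)
  cfg$identity <- TRUE
  new("GeneratorModel", parameters = list(), state = list(), config = cfg,
      normalization = huNormalization())
}

## ---- generator forward / backward ----

## x: (H, W, 1, N) normalized. Returns list(y, st, cache).
generatorForwardCore <- function(par, st, cfg, x, training = TRUE,
                                 keepCache = TRUE) {
  d <- cfg$depth
  f <- cfg$featureSchedule
  sl <- cfg$leakySlopeG
  dims <- dim(x)
  if (dims[1] %% (2^d) || dims[2] %% (2^d))
    stop(sprintf("input size %d x %d is not divisible by 2^depth = %d",
                 dims[1], dims[2], 2^d))
  cache <- list()
  enc <- vector("list", d)
  hp <- vector("list", d)
  for (i in seq_len(d)) {
    a <- cblForward(x, par, st, sprintf("enc%d.ca", i), 1L, 1L, sl,
                    training, keepCache)
    st <- a$st
    b <- cblForward(a$y, par, st, sprintf("enc%d.cb", i), 1L, 1L, sl,
                    training, keepCache)
    st <- b$st
    if (keepCache) cache[[sprintf("enc%d", i)]] <- list(a = a$cache, b = b$cache)
    s <- haarForwardBatch(b$y)
    fi <- f[i]
    enc[[i]] <- b$y
    hp[[i]] <- s[, , (fi + 1L):(4L * fi), , drop = FALSE]
    x <- s[, , seq_len(fi), , drop = FALSE]
  }
  a <- cblForward(x, par, st, "bot.ca", 1L, 1L, sl, training, keepCache)
  st <- a$st
  b <- cblForward(a$y, par, st, "bot.cb", 1L, 1L, sl, training, keepCache)
  st <- b$st
  if (keepCache) cache$bot <- list(a = a$cache, b = b$cache)
  x <- b$y
  for (i in rev(seq_len(d))) {
    p <- cblForward(x, par, st, sprintf("dec%d.cp", i), 1L, 1L, sl,
                    training, keepCache)
    st <- p$st
    u <- haarInverseBatch(catChannels(p$y, hp[[i]]))
    z <- catChannels(u, enc[[i]])
    a <- cblForward(z, par, st, sprintf("dec%d.ca", i), 1L, 1L, sl,
                    training, keepCache)
    st <- a$st
    b <- cblForward(a$y, par, st, sprintf("dec%d.cb", i), 1L, 1L, sl,
                    training, keepCache)
    st <- b$st
    if (keepCache)
      cache[[sprintf("dec%d", i)]] <- list(p = p$cache, a = a$cache,
                                           b = b$cache)
    x <- b$y
  }
  y <- convForward(x, par[["out.w"]], par[["out.b"]], 1L, 0L)
  if (keepCache) cache$outIn <- x
  list(y = y, st = st, cache = cache)
}

## dy: gradient w.r.t. the generator output. Returns flat grads list.
generatorBackwardCore <- function(dy, cache, par, cfg) {
  d <- cfg$depth
  f <- cfg$featureSchedule
  sl <- cfg$leakySlopeG
  grads <- list()
  cb <- convBackward(cache$outIn, par[["out.w"]], dy, 1L, 0L)
  grads[["out.w"]] <- cb$dw; grads[["out.b"]] <- cb$db
  dx <- cb$dx
  dEnc <- vector("list", d)   # gradient flowing into enc features via concat
  dHP <- vector("list", d)
  for (i in seq_len(d)) {
    cc <- cache[[sprintf("dec%d", i)]]
    r <- cblBackward(dx, cc$b, par, sprintf("dec%d.cb", i), 1L, 1L, sl)
    grads <- accumulateGrads(grads, r$grads)
    r <- cblBackward(r$dx, cc$a, par, sprintf("dec%d.ca", i), 1L, 1L, sl)
    grads <- accumulateGrads(grads, r$grads)
    dz <- r$dx
    fi <- f[i]
    du <- dz[, , seq_len(fi), , drop = FALSE]
    dEnc[[i]] <- dz[, , (fi + 1L):(2L * fi), , drop = FALSE]
    ds <- haarForwardBatch(du)          # adjoint of the synthesis
    dp <- ds[, , seq_len(fi), , drop = FALSE]
    dHP[[i]] <- ds[, , (fi + 1L):(4L * fi), , drop = FALSE]
    r <- cblBackward(dp, cc$p, par, sprintf("dec%d.cp", i), 1L, 1L, sl)
    grads <- accumulateGrads(grads, r$grads)
    dx <- r$dx
  }
  r <- cblBackward(dx %||% stop("missing bottleneck gradient"), cache$bot$b,
                   par, "bot.cb", 1L, 1L, sl)
  grads <- accumulateGrads(grads, r$grads)
  r <- cblBackward(r$dx, cache$bot$a, par, "bot.ca", 1L, 1L, sl)
  grads <- accumulateGrads(grads, r$grads)
  dll <- r$dx
  for (i in rev(seq_len(d))) {
    ds <- catChannels(dll, dHP[[i]])
    dbOut <- haarInverseBatch(ds) + dEnc[[i]]   # adjoint of the analysis
    cc <- cache[[sprintf("enc%d", i)]]
    r <- cblBackward(dbOut, cc$b, par, sprintf("enc%d.cb", i), 1L, 1L, sl)
    grads <- accumulateGrads(grads, r$grads)
    r <- cblBackward(r$dx, cc$a, par, sprintf("enc%d.ca", i), 1L, 1L, sl,
                     needDx = i > 1L)
    grads <- accumulateGrads(grads, r$grads)
    dll <- r$dx
  }
  grads
}

## ---- discriminator forward / backward ----

discriminatorForwardCore <- function(par, st, cfg, x, training = TRUE,
                                     keepCache = TRUE) {
  nl <- cfg$discLayers
  sl <- cfg$leakySlopeD
  dims <- dim(x)
  if (min(dims[1], dims[2]) < 2^nl)
    stop(sprintf("input %d x %d too small for %d stride-2 layers",
                 dims[1], dims[2], nl))
  cache <- list()
  for (j in seq_len(nl)) {
    r <- cblForward(x, par, st, sprintf("d%d", j), 2L, 1L, sl, training,
                    keepCache)
    st <- r$st
    if (keepCache) cache[[sprintf("d%d", j)]] <- r$cache
    x <- r$y
  }
  y <- convForward(x, par[["dout.w"]], par[["dout.b"]], 1L, 0L)
  if (keepCache) cache$outIn <- x
  list(y = y, st = st, cache = cache)
}

discriminatorBackwardCore <- function(dy, cache, par, cfg, needDx = TRUE,
                                      needGrads = TRUE) {
  nl <- cfg$discLayers
  sl <- cfg$leakySlopeD
  grads <- list()
  cb <- convBackward(cache$outIn, par[["dout.w"]], dy, 1L, 0L,
                     needDx = TRUE, needDw = needGrads)
  if (needGrads) { grads[["dout.w"]] <- cb$dw; grads[["dout.b"]] <- cb$db }
  dx <- cb$dx
  for (j in rev(seq_len(nl))) {
    r <- cblBackward(dx, cache[[sprintf("d%d", j)]], par, sprintf("d%d", j),
                     2L, 1L, sl, needDx = needDx || j > 1L)
    if (needGrads) grads <- accumulateGrads(grads, r$grads)
    dx <- r$dx
  }
  list(grads = grads, dx = dx)
}

## ---- losses ----

#' Least-squares discriminator loss
#'
#' `0.5 * mean((real - 1)^2) + 0.5 * mean(fake^2)`: zero when the
#' discriminator scores every real patch 1 and every generated patch 0.
#'
#' @param realScores,fakeScores numeric arrays of discriminator scores.
#' @return Non-negative scalar.
#' @export
discriminatorLoss <- function(realScores, fakeScores) {
  if (length(realScores) == 0L || length(fakeScores) == 0L)
    stop("score maps must be non-empty")
  if (!all(is.finite(realScores)) || !all(is.finite(fakeScores)))
    stop("score maps must be finite")
  0.5 * mean((realScores - 1)^2) + 0.5 * mean(fakeScores^2)
}

#' Least-squares generator loss with pixel-wise constraint
#'
#' `0.5 * mean((fakeScores - 1)^2) + lambdaPix * pixelwise(fakePatch,
#' inputPatch)` where the pixel-wise term is the mean squared error by
#' default (`norm = "l2"`) or the mean absolute error (`norm = "l1"`). The
#' pixel term ties the generated patch to its low-dose input so morphology
#' is preserved while the adversarial term pushes the output into the
#' standard-dose domain.
#'
#' @param fakeScores discriminator scores of the generated patches.
#' @param fakePatch,inputPatch generated and source patches, same shape.
#' @param lambdaPix non-negative weight of the pixel-wise term.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return Non-negative scalar.
#' @export
generatorLoss <- function(fakeScores, fakePatch, inputPatch, lambdaPix = 10,
                          norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  if (length(fakeScores) == 0L) stop("score map must be non-empty")
  if (!identical(dim(fakePatch) %||% length(fakePatch),
                 dim(inputPatch) %||% length(inputPatch)))
    stop("fakePatch and inputPatch must share one shape")
  if (lambdaPix < 0) stop("lambdaPix must be non-negative")
  adv <- 0.5 * mean((fakeScores - 1)^2)
  pix <- if (norm == "l2") mean((fakePatch - inputPatch)^2) else
    mean(abs(fakePatch - inputPatch))
  adv + lambdaPix * pix
}

## ---- checkpoints ----

CHECKPOINT_VERSION <- "waveganCT-ckpt-1"

#' Save / load a generator checkpoint
#'
#' The checkpoint embeds the architecture configuration, the HU
#' normalization window, all parameters and batch-norm statistics, the
#' training seed and a format version, so a saved model is self-describing.
#'
#' @param model a [GeneratorModel-class].
#' @param path file path (RDS container).
#' @param seed optional integer recorded for provenance.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the [GeneratorModel-class].
#' @export
saveCheckpoint <- function(model, path, seed = NA_integer_) {
  stopifnot(is(model, "GeneratorModel"))
  saveRDS(list(version = CHECKPOINT_VERSION,
               package = as.character(packageVersion("waveganCT")),
               config = model@config, normalization = model@normalization,
               parameters = model@parameters, state = model@state,
               seed = seed), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", ck$version)
  new("GeneratorModel", parameters = ck$parameters, state = ck$state,
      config = ck$config, normalization = ck$normalization)
}

#' Apply the generator to normalized patches
#'
#' Evaluation-mode forward pass (batch-norm uses running statistics).
#' Inputs and outputs are arrays `(H, W, 1, N)` in normalized units.
#'
#' @param model a [GeneratorModel-class].
#' @param x array `(H, W, 1, N)`.
#' @return Array of the same shape.
#' @export
generatorApply <- function(model, x) {
  if (isTRUE(model@config$identity)) return(x)
  generatorForwardCore(model@parameters, model@state, model@config, x,
                       training = FALSE, keepCache = FALSE)$y
}

#' Apply the discriminator to normalized patches
#'
#' Evaluation-mode scores; on an `L x L` patch the score map has side
#' `L / 2^discLayers`.
#'
#' @param model a [DiscriminatorModel-class].
#' @param x array `(H, W, 1, N)`.
#' @return Score array `(h, w, 1, N)`.
#' @export
discriminatorApply <- function(model, x) {
  discriminatorForwardCore(model@parameters, model@state, model@config, x,
                           training = FALSE, keepCache = FALSE)$y
}
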