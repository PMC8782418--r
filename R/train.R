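## Unpaired adversarial training. Per batch: one discriminator step on
## real standard-dose patches vs. generated (detached) patches, then one
## generator step on the least-squares adversarial term plus the
## pixel-wise constraint to the low-dose input. Patches are sampled at
## independent random offsets from the two corpora, so no positional
## pairing exists anywhere.

#' Training configuration
#'
#' Defaults follow the training protocol of the clinical setting: Adam
#' with learning rate 2e-4, mini-batch of 40 patches, 200 epochs, 128-px
#' patches. Desk-scale runs override `epochs`, `batchSize`, `patchSize`
#' and `patchesPerImage` downwards.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize patches per mini-batch (applies to each domain).
#' @param epochs training epochs; one epoch is one pass over the low-dose
#'   corpus patch budget (`nLD * patchesPerImage` patches).
#' @param lambdaPix weight of the pixel-wise generator term.
#' @param pixelNorm `"l2"` or `"l1"` pixel-wise loss.
#' @param patchSize training patch side; must be divisible by `2^depth` of
#'   the generator.
#' @param patchesPerImage patch budget per low-dose image per epoch.
#' @param seed integer seed for the whole run.
#' @param adamBetas Adam moment decays; `(0.5, 0.999)` as is conventional
#'   for adversarial training.
#' @return Configuration list for [trainVIGAN()].
#' @export
trainConfig <- function(learningRate = 2e-4, batchSize = 40L, epochs = 200L,
                        lambdaPix = 10, pixelNorm = "l2", patchSize = 128L,
                        patchesPerImage = 4L, seed = 1L,
                        adamBetas = c(0.5, 0.999)) {
  if (learningRate <= 0) stop("learningRate must be positive")
  if (batchSize < 1L || epochs < 1L || patchSize < 1L || patchesPerImage < 1L)
    stop("batchSize, epochs, patchSize and patchesPerImage must be positive")
  if (lambdaPix < 0) stop("lambdaPix must be non-negative")
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), lambdaPix = lambdaPix,
       pixelNorm = match.arg(pixelNorm, c("l2", "l1")),
       patchSize = as.integer(patchSize),
       patchesPerImage = as.integer(patchesPerImage),
       seed = as.integer(seed), adamBetas = as.numeric(adamBetas))
}

## Corpus as a list of normalized pixel matrices.
.normalizedCorpus <- function(corpus, norm) {
  lapply(corpus, function(img) {
    m <- if (is(img, "CTImage")) pixels(img) else img
    normalizeHU(m, norm)
  })
}

#' Sample one unpaired training batch
#'
#' Draws `batchSize` patches from each domain independently: image indices
#' uniform over the corpus, patch offsets uniform over the valid range.
#' Uses the ambient RNG stream, so batches are reproducible under
#' `set.seed()`.
#'
#' @param ldCorpus,sdCorpus lists of [CTImage-class] (or matrices, already
#'   normalized inside [trainVIGAN()]).
#' @param cfg a [trainConfig()].
#' @return List with arrays `ld` and `sd` of shape
#'   `(patchSize, patchSize, 1, batchSize)`.
#' @export
sampleTrainingBatch <- function(ldCorpus, sdCorpus, cfg) {
  if (length(ldCorpus) == 0L || length(sdCorpus) == 0L)
    stop("both corpora must be non-empty")
  p <- cfg$patchSize
  draw <- function(corpus) {
    out <- array(0, dim = c(p, p, 1L, cfg$batchSize))
    for (k in seq_len(cfg$batchSize)) {
      m <- corpus[[sample.int(length(corpus), 1L)]]
      if (is(m, "CTImage")) m <- pixels(m)
      if (p > nrow(m) || p > ncol(m))
        stop(sprintf("patch size %d exceeds corpus image size %d x %d",
                     p, nrow(m), ncol(m)))
      r0 <- sample.int(nrow(m) - p + 1L, 1L) - 1L
      c0 <- sample.int(ncol(m) - p + 1L, 1L) - 1L
      out[, , 1L, k] <- m[(r0 + 1L):(r0 + p), (c0 + 1L):(c0 + p)]
    }
    out
  }
  list(ld = draw(ldCorpus), sd = draw(sdCorpus))
}

#' Train the unpaired framelet GAN
#'
#' Alternating least-squares GAN training: per mini-batch one
#' discriminator update (real standard-dose patches scored toward 1,
#' generated patches toward 0) followed by one generator update
#' (adversarial term toward 1 plus `lambdaPix` times the pixel-wise loss
#' against the low-dose input patch). Both networks use Adam. Training
#' aborts with a diagnostic if the generator loss becomes non-finite.
#'
#' @param ldCorpus,sdCorpus lists of [CTImage-class] slices (HU).
#' @param netCfg a [networkConfig()].
#' @param cfg a [trainConfig()]; `cfg$patchSize` must be divisible by
#'   `2^netCfg$depth`.
#' @param verbose print per-epoch losses.
#' @param checkpointPath optional path; when set, a checkpoint is written
#'   every `checkpointEvery` epochs and at the end.
#' @param checkpointEvery cadence in epochs (0 = only final).
#' @return List with `model` (trained [GeneratorModel-class]),
#'   `discriminator` ([DiscriminatorModel-class]) and `history`
#'   ([TrainHistory-class]).
#' @export
trainVIGAN <- function(ldCorpus, sdCorpus, netCfg = networkConfig(),
                       cfg = trainConfig(), verbose = FALSE,
                       checkpointPath = NULL, checkpointEvery = 0L) {
  if (length(ldCorpus) == 0L || length(sdCorpus) == 0L)
    stop("both corpora must be non-empty")
  if (cfg$patchSize %% (2^netCfg$depth))
    stop(sprintf("patch size %d is not divisible by 2^depth = %d",
                 cfg$patchSize, 2^netCfg$depth))
  norm <- huNormalization()
  ldN <- .normalizedCorpus(ldCorpus, norm)
  sdN <- .normalizedCorpus(sdCorpus, norm)

  set.seed(cfg$seed)
  gSeed <- sample.int(.Machine$integer.max, 1L)
  dSeed <- sample.int(.Machine$integer.max, 1L)
  gen <- buildGenerator(netCfg, seed = gSeed)
  dis <- buildDiscriminator(netCfg, seed = dSeed)
  set.seed(cfg$seed + 1L)   # stream for batch sampling

  gPar <- gen@parameters; gSt <- gen@state
  dPar <- dis@parameters; dSt <- dis@state
  gAdam <- adamInit(gPar); dAdam <- adamInit(dPar)

  stepsPerEpoch <- max(1L, ceiling(length(ldN) * cfg$patchesPerImage /
                                     cfg$batchSize))
  gHist <- dHist <- secs <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    gAcc <- dAcc <- 0
    for (step in seq_len(stepsPerEpoch)) {
      b <- sampleTrainingBatch(ldN, sdN, cfg)

      ## generator forward (cached once, reused for the G update)
      gf <- generatorForwardCore(gPar, gSt, netCfg, b$ld, training = TRUE)
      gSt <- gf$st
      fake <- gf$y

      ## --- discriminator step (fake detached) ---
      dfReal <- discriminatorForwardCore(dPar, dSt, netCfg, b$sd,
                                         training = TRUE)
      dSt <- dfReal$st
      dfFake <- discriminatorForwardCore(dPar, dSt, netCfg, fake,
                                         training = TRUE)
      dSt <- dfFake$st
      dLoss <- discriminatorLoss(dfReal$y, dfFake$y)
      nR <- length(dfReal$y); nF <- length(dfFake$y)
      bR <- discriminatorBackwardCore((dfReal$y - 1) / nR, dfReal$cache,
                                      dPar, netCfg, needDx = FALSE)
      bF <- discriminatorBackwardCore(dfFake$y / nF, dfFake$cache,
                                      dPar, netCfg, needDx = FALSE)
      dGrads <- accumulateGrads(bR$grads, bF$grads)
      upd <- adamStep(dPar, dGrads, dAdam, cfg$learningRate, cfg$adamBetas)
      dPar <- upd$par; dAdam <- upd$state

      ## --- generator step (through the updated discriminator) ---
      dfG <- discriminatorForwardCore(dPar, dSt, netCfg, fake,
                                      training = TRUE)
      dSt <- dfG$st
      gLoss <- generatorLoss(dfG$y, fake, b$ld, cfg$lambdaPix,
                             norm = cfg$pixelNorm)
      dScores <- (dfG$y - 1) / length(dfG$y)
      bAdv <- discriminatorBackwardCore(dScores, dfG$cache, dPar, netCfg,
                                        needDx = TRUE, needGrads = FALSE)
      nP <- length(fake)
      dPix <- if (cfg$pixelNorm == "l2")
        2 * cfg$lambdaPix * (fake - b$ld) / nP
      else cfg$lambdaPix * sign(fake - b$ld) / nP
      gGrads <- generatorBackwardCore(bAdv$dx + dPix, gf$cache, gPar, netCfg)
      upd <- adamStep(gPar, gGrads, gAdam, cfg$learningRate, cfg$adamBetas)
      gPar <- upd$par; gAdam <- upd$state

      if (!is.finite(gLoss) || !is.finite(dLoss))
        stop(sprintf("training diverged at epoch %d (J(G)=%g, J(D)=%g)",
                     epoch, gLoss, dLoss))
      gAcc <- gAcc + gLoss; dAcc <- dAcc + dLoss
    }
    gHist[epoch] <- gAcc / stepsPerEpoch
    dHist[epoch] <- dAcc / stepsPerEpoch
    secs[epoch] <- proc.time()[["elapsed"]] - t0
    if (verbose)
      message(sprintf("epoch %3d  J(G)=%.4f  J(D)=%.4f  (%.1fs)", epoch,
                      gHist[epoch], dHist[epoch], secs[epoch]))
    if (!is.null(checkpointPath) && checkpointEvery > 0L &&
        epoch %% checkpointEvery == 0L) {
      gen@parameters <- gPar; gen@state <- gSt
      saveCheckpoint(gen, checkpointPath, seed = cfg$seed)
    }
  }
  gen@parameters <- gPar; gen@state <- gSt
  dis@parameters <- dPar; dis@state <- dSt
  if (!is.null(checkpointPath))
    saveCheckpoint(gen, checkpointPath, seed = cfg$seed)
  list(model = gen,
       discriminator = dis,
       history = new("TrainHistory", gLoss = gHist, dLoss = dHist,
                     seconds = secs))
}

#' Write a training history to CSV
#'
#' Columns `epoch`, `g_loss`, `d_loss`, `seconds`.
#'
#' @param history a [TrainHistory-class].
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
writeTrainLog <- function(history, path) {
  stopifnot(is(history, "TrainHistory"))
  df <- data.frame(epoch = seq_along(history@gLoss),
                   g_loss = history@gLoss, d_loss = history@dLoss,
                   seconds = history@seconds)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
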