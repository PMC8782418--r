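## Patch-based inference: a full slice is cut into overlapping p x p
## windows on a stride-s grid, each window is translated by the generator,
## and the outputs are reassembled with overlapping pixels averaged.
## Offsets are 0-based top-left corners; windows are half-open [o, o + p).

## Offsets along one axis: the arithmetic grid {0, s, 2s, ...}; when
## (dim - p) is not a multiple of s, a final flush-to-edge offset at
## dim - p keeps the border covered.
.axisOffsets <- function(dimension, p, s) {
  last <- dimension - p
  o <- seq.int(0L, last, by = s)
  if (o[length(o)] != last) o <- c(o, last)
  as.integer(o)
}

#' Extract an overlapping patch grid from a slice
#'
#' Cuts `p x p` patches at stride `s` along both axes (the clinical setting
#' is `p = 128`, `s = 32` on a 512 x 512 slice, giving a 13 x 13 grid of
#' 169 patches).
#'
#' @param img a [CTImage-class] or a numeric matrix.
#' @param p patch side in pixels (`p <=` both image dimensions).
#' @param s stride in pixels.
#' @return A [PatchGrid-class]; patches are ordered column-major over the
#'   (row offset, col offset) grid.
#' @export
extractPatches <- function(img, p = 128L, s = 32L) {
  m <- if (is(img, "CTImage")) pixels(img) else img
  p <- as.integer(p); s <- as.integer(s)
  if (p < 1L || s < 1L) stop("patch size and stride must be positive")
  if (p > nrow(m) || p > ncol(m))
    stop(sprintf("patch size %d exceeds image size %d x %d", p, nrow(m),
                 ncol(m)))
  ro <- .axisOffsets(nrow(m), p, s)
  co <- .axisOffsets(ncol(m), p, s)
  offsets <- cbind(rep(ro, times = length(co)),
                   rep(co, each = length(ro)))
  pat <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    r0 <- offsets[i, 1L]; c0 <- offsets[i, 2L]
    pat[[i]] <- m[(r0 + 1L):(r0 + p), (c0 + 1L):(c0 + p)]
  }
  new("PatchGrid", patches = pat, offsets = offsets, patchSize = p,
      stride = s, sourceShape = dim(m))
}

#' Reassemble a patch grid by overlap averaging
#'
#' Each output pixel is the arithmetic mean of every patch value covering
#' it; accumulation runs in extended precision and divides by the exact
#' integer coverage count, so with unmodified patches the round trip is
#' the bit-level identity. A pixel covered by no patch is an error.
#'
#' @param grid a [PatchGrid-class].
#' @return Numeric matrix of shape `sourceShape`.
#' @export
reassemblePatches <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  sz <- grid@sourceShape
  .overlapAverage(grid@patches, grid@offsets, grid@patchSize, sz[1], sz[2])
}

#' Patch coverage counts
#'
#' The number of patches covering each pixel of the source slice; the
#' denominator of the overlap average (e.g. 16 deep in the interior and 1
#' at the corners for the 512/128/32 grid).
#'
#' @param grid a [PatchGrid-class].
#' @return Integer matrix of shape `sourceShape`.
#' @export
patchCoverage <- function(grid) {
  sz <- grid@sourceShape
  p <- grid@patchSize
  cov <- matrix(0L, sz[1], sz[2])
  for (i in seq_along(grid@patches)) {
    r0 <- grid@offsets[i, 1L]; c0 <- grid@offsets[i, 2L]
    cov[(r0 + 1L):(r0 + p), (c0 + 1L):(c0 + p)] <-
      cov[(r0 + 1L):(r0 + p), (c0 + 1L):(c0 + p)] + 1L
  }
  cov
}

#' Denoise a slice with a trained generator
#'
#' Full-slice inference: normalize the slice from HU to the generator's
#' input window, extract the overlapping patch grid, run every patch
#' through the generator (evaluation mode, in batches), reassemble with
#' overlap averaging, and invert the normalization. The result carries
#' `doseLabel = "virtual"`.
#'
#' @param img a [CTImage-class].
#' @param model a trained [GeneratorModel-class] (or [identityGenerator()]).
#' @param p,s patch size and stride.
#' @param batchSize patches per generator call.
#' @return A [CTImage-class] of the same shape.
#' @export
denoiseImage <- function(img, model, p = 128L, s = 32L, batchSize = 32L) {
  stopifnot(is(img, "CTImage"), is(model, "GeneratorModel"))
  cfg <- model@config
  if (!isTRUE(cfg$identity) && p %% (2^cfg$depth))
    stop(sprintf("patch size %d is incompatible with generator depth %d",
                 p, cfg$depth))
  norm <- model@normalization
  m <- normalizeHU(pixels(img), norm)
  grid <- extractPatches(m, p = p, s = s)
  n <- length(grid@patches)
  out <- grid
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    x <- array(unlist(grid@patches[idx], use.names = FALSE),
               dim = c(p, p, 1L, length(idx)))
    y <- generatorApply(model, x)
    for (k in seq_along(idx))
      out@patches[[idx[k]]] <- matrix(y[, , 1L, k], p, p)
  }
  res <- denormalizeHU(reassemblePatches(out), norm)
  CTImage(res, pixelSpacing = pixelSpacing(img), doseLabel = "virtual",
          provenance = sprintf("virtual standard-dose from '%s'",
                               doseLabel(img)))
}
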