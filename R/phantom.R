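## Synthetic abdominal phantoms. A slice is a body ellipse on an air
## background containing a liver ellipse, a portal-vein disc inside the
## liver, and two paraspinal-muscle discs posterior to it. Each region
## draws from a tissue specification (mean HU, optional intra-tissue
## texture SD); a dose profile adds stationary Gaussian noise in HU and a
## multiplicative contrast scale on tissue means, emulating the joint
## noise/contrast difference between 80 kVp low-dose and 120 kVp
## standard-dose acquisitions. Geometry is defined in fractional
## coordinates and scaled to the canvas, with optional per-image jitter so
## corpora are not a fixed layout.

#' Tissue specification
#'
#' @param name region label.
#' @param meanHU mean attenuation in HU, within `[-1024, 3071]`.
#' @param textureSD intra-tissue heterogeneity SD in HU (before dose
#'   noise), `>= 0`.
#' @return A named list used in phantom tissue tables.
#' @export
tissueSpec <- function(name, meanHU, textureSD = 0) {
  if (meanHU < -1024 || meanHU > 3071)
    stop("meanHU must lie within [-1024, 3071]")
  if (textureSD < 0) stop("textureSD must be non-negative")
  list(name = name, meanHU = meanHU, textureSD = textureSD)
}

#' Default tissue tables for the two dose domains
#'
#' Mean attenuations follow the measured organ values of the two domains:
#' low-dose (80 kVp) portal vein 247.3, liver 145.6, paraspinal muscle
#' 75.8 HU with image noise SD 14.2; standard-dose (120 kVp) portal vein
#' 187.6, liver 120.7, muscle 70.7 HU with noise SD 10.6. Generic soft
#' tissue fills the rest of the body.
#'
#' @return A named list of [tissueSpec()] entries.
#' @export
lowDoseTissueTable <- function() list(
  body = tissueSpec("body", 55),
  liver = tissueSpec("liver", 145.6),
  portal_vein = tissueSpec("portal_vein", 247.3),
  muscle_left = tissueSpec("muscle_left", 75.8),
  muscle_right = tissueSpec("muscle_right", 75.8))

#' @rdname lowDoseTissueTable
#' @export
standardDoseTissueTable <- function() list(
  body = tissueSpec("body", 50),
  liver = tissueSpec("liver", 120.7),
  portal_vein = tissueSpec("portal_vein", 187.6),
  muscle_left = tissueSpec("muscle_left", 70.7),
  muscle_right = tissueSpec("muscle_right", 70.7))

## Fractional layout of the default anatomy; (row, col) fractions of the
## canvas. Values chosen so the containment constraints hold with room for
## +/- 5% jitter.
.defaultLayout <- function() list(
  bodyEllipse = list(center = c(0.51, 0.50), axes = c(0.40, 0.44)),
  liverEllipse = list(center = c(0.42, 0.40), axes = c(0.18, 0.21)),
  portalVeinDisc = list(center = c(0.46, 0.45), radius = 0.035),
  muscleDiscLeft = list(center = c(0.76, 0.42), radius = 0.05),
  muscleDiscRight = list(center = c(0.76, 0.58), radius = 0.05))

#' Phantom specification
#'
#' @param imageSize integer(2) canvas size in pixels (rows, cols); the
#'   512 x 512 default matches the clinical slice size, and 128 x 128 is a
#'   convenient small canvas for fast experiments.
#' @param tissueTable named list of [tissueSpec()]s for regions `body`,
#'   `liver`, `portal_vein`, `muscle_left`, `muscle_right`.
#' @param noiseSD dose-noise standard deviation in HU (`>= 0`).
#' @param contrastScale positive multiplier applied to all tissue means
#'   (dose/kVp contrast effect).
#' @param geometry optional geometry in pixel units (as produced by
#'   [phantomGeometry()]); defaults to the standard layout scaled to
#'   `imageSize`.
#' @param pixelSpacing numeric(2) in mm.
#' @return A validated specification list for [makePhantom()].
#' @export
phantomSpec <- function(imageSize = c(512L, 512L),
                        tissueTable = standardDoseTissueTable(),
                        noiseSD = 10.6, contrastScale = 1,
                        geometry = NULL, pixelSpacing = c(0.7, 0.7)) {
  imageSize <- as.integer(imageSize)
  if (length(imageSize) != 2L || any(imageSize < 16L))
    stop("imageSize must be two integers >= 16")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  if (contrastScale <= 0) stop("contrastScale must be positive")
  need <- c("body", "liver", "portal_vein", "muscle_left", "muscle_right")
  if (!all(need %in% names(tissueTable)))
    stop("tissueTable must name regions: ", paste(need, collapse = ", "))
  if (is.null(geometry)) geometry <- phantomGeometry(imageSize)
  spec <- list(imageSize = imageSize, tissueTable = tissueTable,
               noiseSD = noiseSD, contrastScale = contrastScale,
               geometry = geometry, pixelSpacing = as.numeric(pixelSpacing))
  .validateGeometry(spec)
  spec
}

#' Phantom geometry in pixel coordinates
#'
#' Scales the standard fractional layout to a canvas, optionally jittering
#' ellipse/disc centers and axes by independent uniform factors (used to
#' vary anatomy across a corpus).
#'
#' @param imageSize integer(2) canvas size.
#' @param jitter non-negative fraction; axes/radii are scaled by
#'   independent `U(1 - jitter, 1 + jitter)` draws and centers are shifted
#'   by `U(-jitter, jitter)` times the primitive's own extent, so the
#'   perturbation is proportional to the structure being moved
#'   (0 = fixed layout).
#' @return A list of primitives in pixel units: `bodyEllipse`,
#'   `liverEllipse` (center, axes), `portalVeinDisc`, `muscleDiscLeft`,
#'   `muscleDiscRight` (center, radius).
#' @export
phantomGeometry <- function(imageSize, jitter = 0) {
  lay <- .defaultLayout()
  sz <- as.numeric(imageSize)
  scl <- function(n) if (jitter > 0) runif(n, 1 - jitter, 1 + jitter) else rep(1, n)
  shf <- function(n) if (jitter > 0) runif(n, -jitter, jitter) else rep(0, n)
  g <- list()
  for (nm in names(lay)) {
    pr <- lay[[nm]]
    if (!is.null(pr$axes)) {
      axes <- pr$axes * sz * scl(2L)
      g[[nm]] <- list(center = pr$center * sz + axes * shf(2L), axes = axes)
    } else {
      radius <- pr$radius * min(sz) * scl(1L)
      g[[nm]] <- list(center = pr$center * sz + radius * shf(2L),
                      radius = radius)
    }
  }
  g
}

## Containment checks by sampling primitive boundaries.
.ellipseValue <- function(pts, e) {
  ((pts[, 1] - e$center[1]) / e$axes[1])^2 +
    ((pts[, 2] - e$center[2]) / e$axes[2])^2
}

.boundaryPoints <- function(pr, n = 96L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  if (!is.null(pr$axes))
    cbind(pr$center[1] + pr$axes[1] * sin(t), pr$center[2] + pr$axes[2] * cos(t))
  else
    cbind(pr$center[1] + pr$radius * sin(t), pr$center[2] + pr$radius * cos(t))
}

.validateGeometry <- function(spec) {
  g <- spec$geometry
  sz <- spec$imageSize
  for (nm in names(g)) {
    b <- .boundaryPoints(g[[nm]])
    if (any(b < 0) || any(b[, 1] > sz[1] - 1) || any(b[, 2] > sz[2] - 1))
      stop(sprintf("invalid geometry: primitive '%s' extends outside the image",
                   nm))
  }
  if (any(.ellipseValue(.boundaryPoints(g$liverEllipse), g$bodyEllipse) > 1))
    stop("invalid geometry: primitive 'liverEllipse' is not inside the body")
  if (any(.ellipseValue(.boundaryPoints(g$portalVeinDisc), g$liverEllipse) > 1))
    stop("invalid geometry: primitive 'portalVeinDisc' is not inside the liver")
  for (nm in c("muscleDiscLeft", "muscleDiscRight")) {
    if (any(.ellipseValue(.boundaryPoints(g[[nm]]), g$bodyEllipse) > 1))
      stop(sprintf("invalid geometry: primitive '%s' is not inside the body", nm))
    ctr <- matrix(g[[nm]]$center, 1L)
    if (.ellipseValue(ctr, g$liverEllipse) <= 1 ||
        any(.ellipseValue(.boundaryPoints(g[[nm]]), g$liverEllipse) <= 1))
      stop(sprintf("invalid geometry: primitive '%s' intersects the liver", nm))
  }
  invisible(TRUE)
}

.regionLegend <- c(`1` = "body", `2` = "liver", `3` = "portal_vein",
                   `4` = "muscle_left", `5` = "muscle_right")

## Label every pixel center; later regions overwrite earlier ones
## (portal vein over liver over body).
.labelPixels <- function(spec) {
  sz <- spec$imageSize
  g <- spec$geometry
  rows <- matrix(seq_len(sz[1]) - 1, sz[1], sz[2])
  cols <- matrix(seq_len(sz[2]) - 1, sz[1], sz[2], byrow = TRUE)
  insideE <- function(e) ((rows - e$center[1]) / e$axes[1])^2 +
    ((cols - e$center[2]) / e$axes[2])^2 <= 1
  insideD <- function(d) (rows - d$center[1])^2 + (cols - d$center[2])^2 <=
    d$radius^2
  lab <- matrix(0L, sz[1], sz[2])
  lab[insideE(g$bodyEllipse)] <- 1L
  lab[insideE(g$liverEllipse)] <- 2L
  lab[insideD(g$portalVeinDisc)] <- 3L
  lab[insideD(g$muscleDiscLeft)] <- 4L
  lab[insideD(g$muscleDiscRight)] <- 5L
  lab
}

#' Generate one synthetic abdominal phantom slice
#'
#' Renders the labeled anatomy of `spec`, fills each region with
#' `contrastScale * meanHU`, adds per-tissue texture noise (SD
#' `textureSD`) and stationary dose noise (SD `noiseSD`) inside the body,
#' and leaves the air background at exactly -1000 HU. Deterministic given
#' `seed`.
#'
#' @param spec a [phantomSpec()].
#' @param seed integer seed.
#' @param doseLabel dose label recorded on the image.
#' @return A list with elements `image` ([CTImage-class]) and `mask`
#'   ([LabelMask-class]).
#' @export
makePhantom <- function(spec, seed = 1L, doseLabel = "standard") {
  .validateGeometry(spec)
  set.seed(as.integer(seed))
  ph <- .makePhantomNoSeed(spec, doseLabel)
  ph$image@provenance <- sprintf("synthetic phantom (seed %d)", seed)
  ph
}

#' Generate an unpaired two-domain phantom corpus
#'
#' Draws `nLD` low-dose and `nSD` standard-dose slices with independent
#' noise realizations and independent per-image geometry jitter (uniform
#' +/- 5% on centers and axes by default), so the two domains are unpaired
#' by construction. Bit-identical for identical arguments and seed.
#'
#' @param ldSpec,sdSpec [phantomSpec()]s for the two domains.
#' @param nLD,nSD number of slices per domain, `>= 1`.
#' @param seed integer seed.
#' @param jitter per-image geometric jitter fraction.
#' @return A list with `ld` and `sd` (lists of [CTImage-class]) and
#'   `ldMasks`, `sdMasks` (matching [LabelMask-class] lists).
#' @export
makeUnpairedCorpus <- function(ldSpec, sdSpec, nLD, nSD, seed = 1L,
                               jitter = 0.05) {
  if (nLD < 1L || nSD < 1L) stop("corpus sizes must be >= 1")
  set.seed(as.integer(seed))
  gen <- function(spec, n, label) {
    imgs <- vector("list", n); masks <- vector("list", n)
    for (i in seq_len(n)) {
      s <- spec
      ## rejection-sample jitter: rare draws that break the containment
      ## constraints are redrawn rather than propagated
      for (try in 1:100) {
        s$geometry <- phantomGeometry(spec$imageSize, jitter = jitter)
        ok <- tryCatch({ .validateGeometry(s); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        if (try == 100L) stop("could not draw valid jittered geometry")
      }
      ph <- .makePhantomNoSeed(s, label)
      imgs[[i]] <- ph$image; masks[[i]] <- ph$mask
    }
    list(imgs = imgs, masks = masks)
  }
  ld <- gen(ldSpec, nLD, "low")
  sd <- gen(sdSpec, nSD, "standard")
  list(ld = ld$imgs, sd = sd$imgs, ldMasks = ld$masks, sdMasks = sd$masks)
}

## Phantom draw using the ambient RNG stream (corpus-level seeding).
.makePhantomNoSeed <- function(spec, doseLabel) {
  lab <- .labelPixels(spec)
  sz <- spec$imageSize
  px <- matrix(-1000, sz[1], sz[2])
  for (k in seq_along(.regionLegend)) {
    region <- .regionLegend[[k]]
    sel <- lab == k
    n <- sum(sel)
    if (!n) next
    ts <- spec$tissueTable[[region]]
    val <- spec$contrastScale * ts$meanHU
    px[sel] <- if (ts$textureSD > 0) val + rnorm(n, 0, ts$textureSD) else val
  }
  body <- lab > 0L
  if (spec$noiseSD > 0)
    px[body] <- px[body] + rnorm(sum(body), 0, spec$noiseSD)
  list(image = CTImage(px, pixelSpacing = spec$pixelSpacing,
                       doseLabel = doseLabel, provenance = "synthetic phantom"),
       mask = LabelMask(lab, .regionLegend))
}

#' Default circular ROIs for a phantom specification
#'
#' Places the measurement ROIs the quality analysis expects -- one on the
#' portal vein, four on liver parenchyma (avoiding the vein), and one on
#' each paraspinal muscle -- from the phantom geometry, shrunk enough to
#' stay inside their regions.
#'
#' @param spec a [phantomSpec()] (unjittered geometry).
#' @return Named list of [ROISpec-class] objects: `portal_vein`,
#'   `liver_1..liver_4`, `muscle_left`, `muscle_right`.
#' @export
defaultROIs <- function(spec) {
  g <- spec$geometry
  pv <- g$portalVeinDisc
  lv <- g$liverEllipse
  rois <- list(portal_vein = ROISpec("portal_vein", pv$center,
                                     max(2, 0.7 * pv$radius)))
  ## four liver ROIs on a small cross around the liver center, kept away
  ## from the portal vein
  off <- 0.45 * min(lv$axes)
  rl <- max(2.5, 0.22 * min(lv$axes))
  shifts <- list(c(-off, 0), c(off, 0), c(0, -off), c(0, off))
  for (i in 1:4) {
    ctr <- lv$center + shifts[[i]]
    d <- sqrt(sum((ctr - pv$center)^2))
    if (d < pv$radius + rl + 1)  # nudge away from the vein
      ctr <- pv$center + (ctr - pv$center) * (pv$radius + rl + 1.5) / max(d, 1)
    rois[[sprintf("liver_%d", i)]] <- ROISpec(sprintf("liver_%d", i), ctr, rl)
  }
  for (side in c("muscle_left", "muscle_right")) {
    dk <- g[[if (side == "muscle_left") "muscleDiscLeft" else "muscleDiscRight"]]
    rois[[side]] <- ROISpec(side, dk$center, max(2, 0.7 * dk$radius))
  }
  rois
}
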