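## The quantitative image analysis: circular-ROI attenuation statistics,
## image noise SDn (mean paraspinal-muscle SD), CNR = (ROIo - ROIm)/SDn,
## SNR = ROIo/SDn, the intensity-normalized noise power spectrum with AUC
## and peak frequency, and radiation dose-report arithmetic.

.roiPixelIndex <- function(img, roi) {
  m <- pixels(img)
  ctr <- roi@center; r <- roi@radius
  if (ctr[1] - r < 0 || ctr[2] - r < 0 ||
      ctr[1] + r > nrow(m) - 1 || ctr[2] + r > ncol(m) - 1)
    stop(sprintf("ROI '%s' extends outside the image", roi@name))
  r0 <- max(0, floor(ctr[1] - r)); r1 <- min(nrow(m) - 1, ceiling(ctr[1] + r))
  c0 <- max(0, floor(ctr[2] - r)); c1 <- min(ncol(m) - 1, ceiling(ctr[2] + r))
  rows <- (r0:r1)
  cols <- (c0:c1)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2
  cbind(row = rr[inside] + 1L, col = cc[inside] + 1L)
}

#' Circular-ROI statistics
#'
#' Mean, sample standard deviation (denominator n - 1) and pixel count over
#' all pixels whose centers fall inside the circle.
#'
#' @param img a [CTImage-class].
#' @param roi a [ROISpec-class]; must lie fully inside the image.
#' @return List with `mean`, `sd`, `n`.
#' @export
roiStats <- function(img, roi) {
  stopifnot(is(img, "CTImage"), is(roi, "ROISpec"))
  idx <- .roiPixelIndex(img, roi)
  vals <- pixels(img)[idx]
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       n = length(vals))
}

#' Image noise SDn
#'
#' The image noise of a slice: the mean of the sample standard deviations
#' measured in the two paraspinal-muscle ROIs.
#'
#' @param img a [CTImage-class].
#' @param muscleROIs list of exactly two [ROISpec-class] (left and right
#'   paraspinal muscle).
#' @return SDn in HU.
#' @export
imageNoise <- function(img, muscleROIs) {
  if (length(muscleROIs) != 2L)
    stop("imageNoise requires exactly two muscle ROIs")
  mean(vapply(muscleROIs, function(r) roiStats(img, r)$sd, numeric(1)))
}

#' Contrast-to-noise and signal-to-noise ratios
#'
#' Exact closed forms `CNR = (roiO - roiM) / sdn` and `SNR = roiO / sdn`.
#' `sdn = 0` is an undefined-metric error, never an infinity.
#'
#' @param roiO organ mean attenuation (HU).
#' @param roiM paraspinal-muscle mean attenuation (HU).
#' @param sdn image noise (HU), must be > 0.
#' @return Dimensionless ratio.
#' @export
computeCNR <- function(roiO, roiM, sdn) {
  if (!is.finite(sdn) || sdn <= 0)
    stop("CNR is undefined for sdn <= 0")
  (roiO - roiM) / sdn
}

#' @rdname computeCNR
#' @export
computeSNR <- function(roiO, sdn) {
  if (!is.finite(sdn) || sdn <= 0)
    stop("SNR is undefined for sdn <= 0")
  roiO / sdn
}

#' Full quality report for one slice
#'
#' Applies the organ ROI protocol: portal vein from a single ROI, liver as
#' the mean of four parenchymal ROIs, paraspinal muscle as the mean of the
#' two sides; SDn as the mean muscle SD; CNR and SNR for portal vein and
#' liver against the muscle reference.
#'
#' @param img a [CTImage-class].
#' @param rois named list of [ROISpec-class] containing `portal_vein`,
#'   `liver_1..liver_4`, `muscle_left`, `muscle_right` (e.g. from
#'   [defaultROIs()]).
#' @return A [QualityReport-class].
#' @export
qualityReport <- function(img, rois) {
  need <- c("portal_vein", paste0("liver_", 1:4), "muscle_left",
            "muscle_right")
  if (!all(need %in% names(rois)))
    stop("rois must contain: ", paste(need, collapse = ", "))
  stat <- lapply(rois[need], function(r) roiStats(img, r))
  pv <- stat$portal_vein$mean
  liver <- mean(vapply(paste0("liver_", 1:4),
                       function(k) stat[[k]]$mean, numeric(1)))
  muscle <- mean(c(stat$muscle_left$mean, stat$muscle_right$mean))
  noise <- mean(c(stat$muscle_left$sd, stat$muscle_right$sd))
  means <- c(portal_vein = pv, liver = liver, muscle = muscle)
  if (noise > 0) {
    cnrv <- c(portal_vein = computeCNR(pv, muscle, noise),
              liver = computeCNR(liver, muscle, noise))
    snrv <- c(portal_vein = computeSNR(pv, noise),
              liver = computeSNR(liver, noise))
  } else {
    cnrv <- snrv <- setNames(numeric(0), character(0))
  }
  new("QualityReport", roiMeans = means, sdn = noise, cnr = cnrv, snr = snrv)
}

## Non-overlapping tile anchors fully inside a mask region.
.npsTiles <- function(lab, region, patch) {
  sel <- lab == region
  anchors <- list()
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < patch || nc < patch) return(anchors)
  ## column sums over a sliding window via cumulative sums
  cs <- rbind(0, apply(sel, 2, cumsum))
  for (r0 in seq.int(1L, nr - patch + 1L, by = patch)) {
    colFull <- (cs[r0 + patch, ] - cs[r0, ]) == patch
    ccs <- c(0, cumsum(colFull))
    for (c0 in seq.int(1L, nc - patch + 1L, by = patch)) {
      if (ccs[c0 + patch] - ccs[c0] == patch)
        anchors[[length(anchors) + 1L]] <- c(r0, c0)
    }
  }
  anchors
}

#' Noise power spectrum of a homogeneous region
#'
#' Tiles the region with non-overlapping `patch x patch` windows fully
#' inside the mask, normalizes each tile to its mean intensity (divide by
#' the mean, subtract 1), computes the squared-magnitude 2-D DFT scaled by
#' pixel area over tile pixel count, averages across tiles, and radially
#' averages the 2-D spectrum into bins one DFT step wide. The AUC is the
#' trapezoidal integral of the radial curve and the peak frequency the
#' location of the maximum magnitude with the DC bin excluded and ties
#' broken toward the lowest frequency. Because tiles are mean-normalized
#' the spectrum is intensity-normalized (relative NPS) and invariant to a
#' global intensity offset in the region mean sense.
#'
#' @param img a [CTImage-class].
#' @param mask a [LabelMask-class] for the image.
#' @param region region name or label value selecting the homogeneous
#'   tissue (default `"liver"`).
#' @param patch tile side in pixels.
#' @return An [NPSResult-class]; frequencies in cycles/mm when the image
#'   has pixel spacing, else cycles/pixel.
#' @export
computeNPS <- function(img, mask, region = "liver", patch = 32L) {
  stopifnot(is(img, "CTImage"), is(mask, "LabelMask"))
  lab <- labelMatrix(mask)
  if (!identical(dim(lab), dim(pixels(img))))
    stop("mask shape does not match the image")
  if (is.character(region)) {
    hit <- names(maskLegend(mask))[maskLegend(mask) == region]
    if (!length(hit)) stop("region '", region, "' not in the mask legend")
    region <- as.integer(hit[1L])
  }
  patch <- as.integer(patch)
  anchors <- .npsTiles(lab, region, patch)
  if (!length(anchors))
    stop(sprintf("region admits no full %d x %d tile", patch, patch))
  sp <- pixelSpacing(img)
  dx <- sp[1]; dy <- sp[2]
  m <- pixels(img)
  spec <- matrix(0, patch, patch)
  for (a in anchors) {
    tile <- m[a[1]:(a[1] + patch - 1L), a[2]:(a[2] + patch - 1L)]
    d <- tile / mean(tile) - 1
    F <- fft(d)
    spec <- spec + (Mod(F)^2) * (dx * dy) / (patch * patch)
  }
  spec <- spec / length(anchors)
  mass <- sum(spec) / (patch * dx * patch * dy)  # = relative variance (Parseval)

  ## radial average over the centered spectrum; bin width = one DFT step
  fstep <- 1 / (patch * dx)
  k <- c(0:(patch %/% 2), -((patch - (patch %/% 2 + 1)):1))
  fr <- sqrt(outer((k / (patch * dx))^2, (k / (patch * dy))^2, "+"))
  bins <- round(fr / fstep)
  nb <- max(bins) + 1L
  mag <- vapply(0:(nb - 1L), function(b) mean(spec[bins == b]), numeric(1))
  freqs <- (0:(nb - 1L)) * fstep
  auc <- if (nb > 1L) sum(diff(freqs) * (utils::head(mag, -1) +
                                           utils::tail(mag, -1)) / 2) else 0
  peakIdx <- if (nb > 1L) 1L + which.max(mag[-1L]) else 1L
  new("NPSResult", frequencies = freqs, magnitudes = pmax(mag, 0),
      auc = auc, peakFrequency = freqs[peakIdx], spectralMass = mass,
      units = if (all(sp == 1)) "cycles/pixel" else "cycles/mm")
}

#' Radiation dose records and dose-reduction report
#'
#' `doseRecord()` builds one acquisition's dose entry; `ED = DLP x K` when
#' the conversion factor is supplied. `doseReport()` compares the
#' per-group means of standard-dose and low-dose records and reports the
#' percent reduction `(mean_sd - mean_ld) / mean_sd * 100` for CTDIvol,
#' DLP and ED, rounded to one decimal for display.
#'
#' @param ctdiVol volume CT dose index (mGy).
#' @param dlp dose-length product (mGy cm).
#' @param kFactor tissue-weighting conversion factor (mSv per mGy cm).
#' @param ed effective dose (mSv); computed as `dlp * kFactor` when
#'   omitted and `kFactor` is given.
#' @return `doseRecord()`: one-row data.frame with columns `ctdi_vol`,
#'   `dlp`, `ed`.
#' @export
doseRecord <- function(ctdiVol, dlp, kFactor = NA_real_, ed = NA_real_) {
  if (ctdiVol < 0 || dlp < 0) stop("dose quantities must be non-negative")
  if (is.na(ed)) {
    if (!is.na(kFactor)) ed <- dlp * kFactor
  } else if (!is.na(kFactor) && abs(ed - dlp * kFactor) > 1e-6 * max(1, ed)) {
    stop("ed is inconsistent with dlp * kFactor")
  }
  data.frame(ctdi_vol = ctdiVol, dlp = dlp, ed = ed)
}

#' @rdname doseRecord
#' @param recordsSD,recordsLD data.frames of dose records (rows from
#'   [doseRecord()], possibly rbind-ed) for the standard-dose and low-dose
#'   groups.
#' @return `doseReport()`: data.frame with one row per metric and columns
#'   `metric`, `mean_sd`, `mean_ld`, `reduction_pct` (one decimal).
#' @export
doseReport <- function(recordsSD, recordsLD) {
  if (!nrow(recordsSD) || !nrow(recordsLD))
    stop("both record sets must be non-empty")
  metrics <- c("ctdi_vol", "dlp", "ed")
  out <- data.frame(metric = metrics, mean_sd = NA_real_,
                    mean_ld = NA_real_, reduction_pct = NA_real_)
  for (i in seq_along(metrics)) {
    ms <- mean(recordsSD[[metrics[i]]], na.rm = TRUE)
    ml <- mean(recordsLD[[metrics[i]]], na.rm = TRUE)
    if (!is.finite(ms) || ms == 0)
      stop("reduction is undefined for zero/absent standard-dose mean of ",
           metrics[i])
    out$mean_sd[i] <- ms
    out$mean_ld[i] <- ml
    out$reduction_pct[i] <- round((ms - ml) / ms * 100, 1)
  }
  out
}

#' Evaluate a set of slices into a CSV-ready table
#'
#' Runs [qualityReport()] on every image and returns one row per image
#' with ROI means, SDn, CNR and SNR.
#'
#' @param imgs list of [CTImage-class].
#' @param rois named ROI list as for [qualityReport()].
#' @param ids optional row identifiers.
#' @return data.frame with one row per image.
#' @export
evaluateImages <- function(imgs, rois, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(imgs))
  rows <- lapply(seq_along(imgs), function(i) {
    q <- qualityReport(imgs[[i]], rois)
    data.frame(id = ids[i], dose = doseLabel(imgs[[i]]),
               portal_vein_hu = roiMeans(q)[["portal_vein"]],
               liver_hu = roiMeans(q)[["liver"]],
               muscle_hu = roiMeans(q)[["muscle"]],
               sdn = sdn(q),
               cnr_portal_vein = cnr(q)[["portal_vein"]],
               cnr_liver = cnr(q)[["liver"]],
               snr_portal_vein = snr(q)[["portal_vein"]],
               snr_liver = snr(q)[["liver"]])
  })
  do.call(rbind, rows)
}
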