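## Central S4 containers. All images are single axial slices in Hounsfield
## units; matrices are indexed [row, col] and pixel coordinates are 0-based
## (row, col) pairs referring to pixel centers.

#' CTImage: a single CT slice in Hounsfield units
#'
#' Holds a 2-D pixel matrix in HU together with the in-plane pixel spacing
#' (mm) and a dose label distinguishing original low-dose input (`"low"`),
#' real standard-dose (`"standard"`) and generator output (`"virtual"`).
#'
#' @slot pixels numeric matrix of HU values, finite everywhere.
#' @slot pixelSpacing numeric(2), (row, col) spacing in mm, both > 0.
#' @slot doseLabel one of `"low"`, `"standard"`, `"virtual"`.
#' @slot provenance free-text description of how the slice was produced.
#' @export
setClass("CTImage",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 doseLabel = "character", provenance = "character"),
  prototype(pixelSpacing = c(1, 1), doseLabel = "low", provenance = ""))

setValidity("CTImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || nrow(p) < 1L || ncol(p) < 1L)
    return("pixels must be a non-empty numeric matrix")
  if (!all(is.finite(p)))
    return("pixels must be finite everywhere")
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive numbers (mm)")
  if (length(object@doseLabel) != 1L ||
      !object@doseLabel %in% c("low", "standard", "virtual"))
    return("doseLabel must be one of 'low', 'standard', 'virtual'")
  TRUE
})

#' Construct a CTImage
#'
#' @param pixels numeric matrix of HU values.
#' @param pixelSpacing numeric(2) in mm (row, col).
#' @param doseLabel `"low"`, `"standard"` or `"virtual"`.
#' @param provenance free text recorded with the image.
#' @return A [CTImage-class] object.
#' @examples
#' img <- CTImage(matrix(0, 32, 32))
#' dim(pixels(img))
#' @export
CTImage <- function(pixels, pixelSpacing = c(1, 1), doseLabel = "low",
                    provenance = "") {
  new("CTImage", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing),
      doseLabel = doseLabel, provenance = provenance)
}

#' LabelMask: per-pixel region labels for a CTImage
#'
#' @slot labels integer matrix, 0 = background/air; same shape as the image
#'   it describes.
#' @slot legend named character vector mapping label values (as names) to
#'   region names.
#' @export
setClass("LabelMask",
  representation(labels = "matrix", legend = "character"))

setValidity("LabelMask", function(object) {
  lab <- object@labels
  if (!is.numeric(lab)) return("labels must be an integer matrix")
  used <- sort(unique(as.integer(lab[lab != 0])))
  if (length(used) && !all(as.character(used) %in% names(object@legend)))
    return("every nonzero label must appear in the legend")
  TRUE
})

#' @rdname LabelMask-class
#' @param labels integer matrix of region labels.
#' @param legend named character vector (names are label values).
#' @export
LabelMask <- function(labels, legend) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, legend = legend)
}

#' SubbandSet: one level of 2-D Haar subbands
#'
#' The four subbands of a single-level 2-D Haar analysis of an even-sized
#' matrix: `ll` (approximation), `lh` (detail along width), `hl` (detail
#' along height), `hh` (diagonal detail). Under the orthonormal convention
#' used here every filter tap is +/- 1/2, so the analysis is an orthogonal
#' map: energy is conserved and synthesis is its transpose.
#'
#' @slot ll,lh,hl,hh numeric matrices of identical shape.
#' @slot orthonormal logical flag recording the filter convention.
#' @export
setClass("SubbandSet",
  representation(ll = "matrix", lh = "matrix", hl = "matrix", hh = "matrix",
                 orthonormal = "logical"),
  prototype(orthonormal = TRUE))

setValidity("SubbandSet", function(object) {
  d <- dim(object@ll)
  for (s in c("lh", "hl", "hh"))
    if (!identical(dim(slot(object, s)), d))
      return("all four subbands must share one shape")
  TRUE
})

#' PatchGrid: a slice cut into overlapping patches
#'
#' @slot patches list of p x p numeric matrices in grid order.
#' @slot offsets integer matrix (n x 2) of 0-based (row, col) top-left
#'   corners; windows are half-open `[o, o + p)`.
#' @slot patchSize,stride integers.
#' @slot sourceShape integer(2), shape of the source slice.
#' @export
setClass("PatchGrid",
  representation(patches = "list", offsets = "matrix",
                 patchSize = "integer", stride = "integer",
                 sourceShape = "integer"))

setValidity("PatchGrid", function(object) {
  p <- object@patchSize
  if (nrow(object@offsets) != length(object@patches))
    return("offsets and patches disagree in length")
  if (any(object@offsets < 0) ||
      any(object@offsets[, 1] > object@sourceShape[1] - p) ||
      any(object@offsets[, 2] > object@sourceShape[2] - p))
    return("offsets place patches outside the source image")
  TRUE
})

#' GeneratorModel / DiscriminatorModel: network containers
#'
#' `GeneratorModel` holds the deep convolutional framelet generator G;
#' `DiscriminatorModel` the strided patch discriminator D. Both store a flat
#' named list of parameter arrays, batch-normalization running statistics,
#' and the architecture configuration from [networkConfig()]. The generator
#' additionally records the HU normalization window so that denoising is
#' exactly invertible in HU.
#'
#' @slot parameters named list of numeric arrays (trainable).
#' @slot state named list of batch-norm running means/variances.
#' @slot config list from [networkConfig()].
#' @slot normalization list with `center` and `scale` (HU -> [-1, 1] map).
#' @aliases DiscriminatorModel-class
#' @export
setClass("GeneratorModel",
  representation(parameters = "list", state = "list", config = "list",
                 normalization = "list"))

#' @rdname GeneratorModel-class
#' @export
setClass("DiscriminatorModel",
  representation(parameters = "list", state = "list", config = "list"))

#' ROISpec: a circular region of interest
#'
#' Circles are defined in 0-based pixel coordinates; a pixel belongs to the
#' ROI when its center lies inside or on the circle.
#'
#' @slot name organ label (e.g. `"portal_vein"`, `"liver_1"`, `"muscle_left"`).
#' @slot center numeric(2), 0-based (row, col) of the circle center.
#' @slot radius positive radius in pixels.
#' @export
setClass("ROISpec",
  representation(name = "character", center = "numeric", radius = "numeric"))

setValidity("ROISpec", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0) return("radius must be a positive number")
  TRUE
})

#' @rdname ROISpec-class
#' @param name organ label.
#' @param center numeric(2) 0-based (row, col).
#' @param radius radius in pixels.
#' @export
ROISpec <- function(name, center, radius) {
  new("ROISpec", name = name, center = as.numeric(center),
      radius = as.numeric(radius))
}

#' QualityReport: per-image quantitative quality metrics
#'
#' ROI attenuation means, image noise SDn (mean paraspinal-muscle SD), and
#' the derived contrast-to-noise and signal-to-noise ratios
#' CNR = (ROIo - ROIm) / SDn, SNR = ROIo / SDn.
#'
#' @slot roiMeans named numeric, mean HU per organ.
#' @slot sdn image noise in HU (>= 0).
#' @slot cnr,snr named numeric, one entry per organ with a measured mean
#'   (excluding muscle, which is the reference).
#' @export
setClass("QualityReport",
  representation(roiMeans = "numeric", sdn = "numeric",
                 cnr = "numeric", snr = "numeric"))

setValidity("QualityReport", function(object) {
  if (length(object@sdn) != 1L || object@sdn < 0)
    return("sdn must be a single non-negative number")
  if (!all(names(object@cnr) %in% names(object@roiMeans)) ||
      !all(names(object@snr) %in% names(object@roiMeans)))
    return("cnr/snr entries must correspond to measured ROI means")
  TRUE
})

#' NPSResult: radially averaged noise power spectrum
#'
#' @slot frequencies increasing non-negative radial frequencies
#'   (cycles/mm when pixel spacing is known, else cycles/pixel).
#' @slot magnitudes non-negative NPS magnitudes, one per frequency bin.
#' @slot auc trapezoidal area under the radial curve.
#' @slot peakFrequency frequency of the maximum magnitude (DC excluded,
#'   lowest-frequency tie-break).
#' @slot spectralMass 2-D integral of the NPS over the frequency plane; by
#'   Parseval this equals the relative variance of the mean-normalized
#'   fluctuation field.
#' @slot units `"cycles/mm"` or `"cycles/pixel"`.
#' @export
setClass("NPSResult",
  representation(frequencies = "numeric", magnitudes = "numeric",
                 auc = "numeric", peakFrequency = "numeric",
                 spectralMass = "numeric", units = "character"))

setValidity("NPSResult", function(object) {
  if (length(object@frequencies) != length(object@magnitudes))
    return("frequencies and magnitudes must have equal length")
  if (is.unsorted(object@frequencies)) return("frequencies must increase")
  if (any(object@magnitudes < -1e-12)) return("magnitudes must be non-negative")
  TRUE
})

#' TrainHistory: per-epoch loss trace of an adversarial run
#'
#' @slot gLoss,dLoss numeric vectors, mean generator / discriminator loss
#'   per completed epoch.
#' @slot seconds wall-clock seconds per epoch.
#' @export
setClass("TrainHistory",
  representation(gLoss = "numeric", dLoss = "numeric", seconds = "numeric"))

setValidity("TrainHistory", function(object) {
  if (length(object@dLoss) != length(object@gLoss) ||
      length(object@seconds) != length(object@gLoss))
    return("history vectors must have one entry per completed epoch")
  TRUE
})
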