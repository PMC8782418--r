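#' Accessors for the package's S4 containers
#'
#' Small generic accessors so slots are never reached into directly:
#' `pixels()`, `pixelSpacing()`, `doseLabel()`, `provenance()` for
#' [CTImage-class]; `labelMatrix()`/`maskLegend()` for [LabelMask-class];
#' `subband()` for [SubbandSet-class]; `patches()`/`patchOffsets()` for
#' [PatchGrid-class]; `modelConfig()`/`modelParameters()` for the network
#' containers; `roiMeans()`, `sdn()`, `cnr()`, `snr()` for
#' [QualityReport-class]; `npsFrequencies()`, `npsMagnitudes()`, `npsAUC()`,
#' `peakFrequency()` for [NPSResult-class]; and `lossHistory()` for
#' [TrainHistory-class].
#'
#' @param object an object of the documented class.
#' @param ... unused.
#' @return The slot contents (see each class's documentation).
#' @name accessors
#' @aliases pixels pixelSpacing doseLabel provenance labelMatrix maskLegend
#'   subband patches patchOffsets modelConfig modelParameters roiMeans sdn
#'   cnr snr npsFrequencies npsMagnitudes npsAUC peakFrequency lossHistory
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("doseLabel", function(object) standardGeneric("doseLabel"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskLegend", function(object) standardGeneric("maskLegend"))
#' @rdname accessors
#' @param which for `subband()`, one of `"ll"`, `"lh"`, `"hl"`, `"hh"`;
#'   for `lossHistory()`, `"generator"`, `"discriminator"` or `"seconds"`.
#' @export
setGeneric("subband", function(object, which = c("ll", "lh", "hl", "hh"))
  standardGeneric("subband"))
#' @rdname accessors
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))
#' @rdname accessors
#' @export
setGeneric("patchOffsets", function(object) standardGeneric("patchOffsets"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("modelParameters", function(object) standardGeneric("modelParameters"))
#' @rdname accessors
#' @export
setGeneric("roiMeans", function(object) standardGeneric("roiMeans"))
#' @rdname accessors
#' @export
setGeneric("sdn", function(object) standardGeneric("sdn"))
#' @rdname accessors
#' @export
setGeneric("cnr", function(object) standardGeneric("cnr"))
#' @rdname accessors
#' @export
setGeneric("snr", function(object) standardGeneric("snr"))
#' @rdname accessors
#' @export
setGeneric("npsFrequencies", function(object) standardGeneric("npsFrequencies"))
#' @rdname accessors
#' @export
setGeneric("npsMagnitudes", function(object) standardGeneric("npsMagnitudes"))
#' @rdname accessors
#' @export
setGeneric("npsAUC", function(object) standardGeneric("npsAUC"))
#' @rdname accessors
#' @export
setGeneric("peakFrequency", function(object) standardGeneric("peakFrequency"))
#' @rdname accessors
#' @export
setGeneric("npsSpectralMass", function(object) standardGeneric("npsSpectralMass"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object, which = c("generator",
  "discriminator", "seconds")) standardGeneric("lossHistory"))

## ---- methods ----

#' @rdname accessors
setMethod("pixels", "CTImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelSpacing", "CTImage", function(object) object@pixelSpacing)
#' @rdname accessors
setMethod("doseLabel", "CTImage", function(object) object@doseLabel)
#' @rdname accessors
setMethod("provenance", "CTImage", function(object) object@provenance)
#' @rdname accessors
setMethod("labelMatrix", "LabelMask", function(object) object@labels)
#' @rdname accessors
setMethod("maskLegend", "LabelMask", function(object) object@legend)
#' @rdname accessors
setMethod("subband", "SubbandSet", function(object, which = c("ll", "lh",
  "hl", "hh")) slot(object, match.arg(which)))
#' @rdname accessors
setMethod("patches", "PatchGrid", function(object) object@patches)
#' @rdname accessors
setMethod("patchOffsets", "PatchGrid", function(object) object@offsets)
#' @rdname accessors
setMethod("modelConfig", "GeneratorModel", function(object) object@config)
#' @rdname accessors
setMethod("modelConfig", "DiscriminatorModel", function(object) object@config)
#' @rdname accessors
setMethod("modelParameters", "GeneratorModel", function(object) object@parameters)
#' @rdname accessors
setMethod("modelParameters", "DiscriminatorModel", function(object) object@parameters)
#' @rdname accessors
setMethod("roiMeans", "QualityReport", function(object) object@roiMeans)
#' @rdname accessors
setMethod("sdn", "QualityReport", function(object) object@sdn)
#' @rdname accessors
setMethod("cnr", "QualityReport", function(object) object@cnr)
#' @rdname accessors
setMethod("snr", "QualityReport", function(object) object@snr)
#' @rdname accessors
setMethod("npsFrequencies", "NPSResult", function(object) object@frequencies)
#' @rdname accessors
setMethod("npsMagnitudes", "NPSResult", function(object) object@magnitudes)
#' @rdname accessors
setMethod("npsAUC", "NPSResult", function(object) object@auc)
#' @rdname accessors
setMethod("peakFrequency", "NPSResult", function(object) object@peakFrequency)
#' @rdname accessors
setMethod("npsSpectralMass", "NPSResult", function(object) object@spectralMass)
#' @rdname accessors
setMethod("lossHistory", "TrainHistory", function(object,
    which = c("generator", "discriminator", "seconds")) {
  switch(match.arg(which), generator = object@gLoss,
         discriminator = object@dLoss, seconds = object@seconds)
})

## ---- show methods ----

setMethod("show", "CTImage", function(object) {
  cat(sprintf("CTImage: %d x %d px, spacing %.3g x %.3g mm, dose '%s'\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@doseLabel))
  cat(sprintf("  HU range [%.1f, %.1f]%s\n", min(object@pixels),
              max(object@pixels),
              if (nzchar(object@provenance))
                paste0("; provenance: ", object@provenance) else ""))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, regions: %s\n", nrow(object@labels),
              ncol(object@labels), paste(object@legend, collapse = ", ")))
})

setMethod("show", "SubbandSet", function(object) {
  cat(sprintf("SubbandSet: 4 subbands of %d x %d (%s Haar)\n",
              nrow(object@ll), ncol(object@ll),
              if (object@orthonormal) "orthonormal" else "unnormalized"))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %d px, stride %d, from %d x %d\n",
              length(object@patches), object@patchSize, object@stride,
              object@sourceShape[1], object@sourceShape[2]))
})

setMethod("show", "GeneratorModel", function(object) {
  np <- sum(vapply(object@parameters, length, 1L))
  cat(sprintf("GeneratorModel: framelet encoder-decoder, depth %d, %s parameters\n",
              object@config$depth, format(np, big.mark = ",")))
})

setMethod("show", "DiscriminatorModel", function(object) {
  np <- sum(vapply(object@parameters, length, 1L))
  cat(sprintf("DiscriminatorModel: %d strided conv layers, %s parameters\n",
              object@config$discLayers, format(np, big.mark = ",")))
})

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n  ROI means (HU):",
      paste(sprintf("%s=%.1f", names(object@roiMeans), object@roiMeans),
            collapse = ", "),
      sprintf("\n  SDn=%.2f HU;", object@sdn),
      "CNR:", paste(sprintf("%s=%.2f", names(object@cnr), object@cnr),
                    collapse = ", "),
      "; SNR:", paste(sprintf("%s=%.2f", names(object@snr), object@snr),
                      collapse = ", "), "\n")
})

setMethod("show", "NPSResult", function(object) {
  cat(sprintf("NPSResult: %d radial bins (%s), AUC %.4g, peak at %.4g\n",
              length(object@frequencies), object@units, object@auc,
              object@peakFrequency))
})

setMethod("show", "TrainHistory", function(object) {
  n <- length(object@gLoss)
  cat(sprintf("TrainHistory: %d epochs, final J(G)=%.4g, J(D)=%.4g\n",
              n, if (n) object@gLoss[n] else NA, if (n) object@dLoss[n] else NA))
})
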