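## Accessors and show() methods.

#' @describeIn SpectralFrameStack-class intensity array accessor
#' @param object a `SpectralFrameStack`
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))
#' @export
setMethod("stackData", "SpectralFrameStack", function(object) object@data)

#' @describeIn SpectralFrameStack-class band wavelengths in nm
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @export
setMethod("wavelengths", "SpectralFrameStack",
          function(object) object@wavelengths_nm)
#' @export
setMethod("wavelengths", "ChromophoreBasis",
          function(object) object@wavelengths_nm)

#' @describeIn SpectralFrameStack-class frame rate in Hz
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @export
setMethod("frameRate", "SpectralFrameStack",
          function(object) object@frame_rate_hz)

#' @describeIn SpectralFrameStack-class subject label
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "SpectralFrameStack", function(object) object@subject_id)

#' @describeIn ROICatalog-class named list of logical masks
#' @param object an `ROICatalog`
#' @export
setGeneric("roiMasks", function(object) standardGeneric("roiMasks"))
#' @export
setMethod("roiMasks", "ROICatalog", function(object) object@masks)

#' @describeIn ROICatalog-class ROI names
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @export
setMethod("roiNames", "ROICatalog", function(object) names(object@masks))

#' Design matrix of a chromophore basis
#'
#' Returns the B x 4 matrix `[eps_hbo2 | eps_hb | eps_melanin | 1]` whose
#' last all-ones column absorbs the wavelength-flat offset G'.
#'
#' @param object a [ChromophoreBasis-class]
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @export
setMethod("designMatrix", "ChromophoreBasis", function(object) {
  m <- cbind(object@eps_hbo2, object@eps_hb, object@eps_melanin,
             rep(1, length(object@wavelengths_nm)))
  colnames(m) <- c("hbo2", "hb", "melanin", "gprime")
  m
})

#' @describeIn StO2Stack-class StO2 array accessor
#' @param object an `StO2Stack`
#' @export
setGeneric("sto2Values", function(object) standardGeneric("sto2Values"))
#' @export
setMethod("sto2Values", "StO2Stack", function(object) object@sto2)

#' @describeIn Codebook-class M x D matrix of visual words
#' @param object a `Codebook`
#' @export
setGeneric("codewords", function(object) standardGeneric("codewords"))
#' @export
setMethod("codewords", "Codebook", function(object) object@words)

setMethod("show", "SpectralFrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SpectralFrameStack '%s': %d frames x %d bands x %d x %d @ %.1f Hz\n",
    object@subject_id, d[1], d[2], d[3], d[4], object@frame_rate_hz))
  cat("  wavelengths (nm):", paste(object@wavelengths_nm, collapse = ", "),
      "\n")
})

setMethod("show", "ROICatalog", function(object) {
  d <- dim(object@masks[[1]])
  cat(sprintf("ROICatalog: %d masks on a %d x %d grid\n",
              length(object@masks), d[1], d[2]))
  px <- vapply(object@masks, sum, numeric(1))
  cat(" ", paste(sprintf("%s(%d px)", names(px), px), collapse = ", "), "\n")
})

setMethod("show", "ChromophoreBasis", function(object) {
  cat("ChromophoreBasis over", length(object@wavelengths_nm), "bands\n")
  print(designMatrix(object))
})

setMethod("show", "ChromophoreMap", function(object) {
  d <- dim(object@c_hbo2)
  cat(sprintf("ChromophoreMap: %d frames x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  mean c_hbo2 %.4g, c_hb %.4g, c_melanin %.4g, G' %.4g\n",
              mean(object@c_hbo2), mean(object@c_hb), mean(object@c_melanin),
              mean(object@g_prime)))
})

setMethod("show", "StO2Stack", function(object) {
  d <- dim(object@sto2)
  cat(sprintf("StO2Stack: %d frames x %d x %d, mean StO2 %.3f (%.1f%% NaN)\n",
              d[1], d[2], d[3], mean(object@sto2, na.rm = TRUE),
              100 * mean(is.nan(object@sto2))))
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d words x %d dims (seed %d, %d iterations)\n",
              nrow(object@words), ncol(object@words), object@seed,
              object@iterations))
})

setMethod("show", "MSMGraph", function(object) {
  cat(sprintf("MSMGraph: %d codewords in 5 layers (sizes %s)\n",
              length(object@layer),
              paste(tabulate(object@layer, 5), collapse = "/")))
})
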