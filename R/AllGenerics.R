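#' @rdname SamplingMask-class
#' @param object a package object.
#' @export
setGeneric("maskShape", function(object) standardGeneric("maskShape"))

#' @rdname SamplingMask-class
#' @export
setGeneric("maskIndices", function(object) standardGeneric("maskIndices"))

#' @rdname SamplingMask-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname WaveletCoeffs-class
#' @param object a package object.
#' @export
setGeneric("coeffArray", function(object) standardGeneric("coeffArray"))

#' @rdname THzPhantom-class
#' @param object a package object.
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))

#' @rdname THzReconstruction-class
#' @param object a package object.
#' @export
setGeneric("reconImage", function(object) standardGeneric("reconImage"))

#' @rdname THzReconstruction-class
#' @export
setGeneric("reconDiagnostics",
           function(object) standardGeneric("reconDiagnostics"))

#' @describeIn SamplingMask-class image grid dimensions.
setMethod("maskShape", "SamplingMask", function(object) object@shape)

#' @describeIn SamplingMask-class M x 2 matrix of 1-based (row, col)
#'   coordinates in canonical raster order.
setMethod("maskIndices", "SamplingMask", function(object) object@indices)

#' @describeIn SamplingMask-class realized sampling fraction M/N.
setMethod("samplingRate", "SamplingMask",
          function(object) nrow(object@indices) / prod(object@shape))

#' @describeIn WaveletCoeffs-class the subband array (rows x cols x
#'   subbands).
setMethod("coeffArray", "WaveletCoeffs", function(object) object@coeffs)

#' @describeIn ExpCoeffs-class the signed exponential coefficient array.
setMethod("coeffArray", "ExpCoeffs", function(object) object@values)

#' @describeIn GroupCoeffs-class the L^2 x c x P coefficient array.
setMethod("coeffArray", "GroupCoeffs", function(object) object@values)

#' @describeIn THzPhantom-class the phantom image matrix.
setMethod("phantomImage", "THzPhantom", function(object) object@image)

#' @describeIn THzReconstruction-class the reconstructed image matrix.
setMethod("reconImage", "THzReconstruction", function(object) object@image)

#' @describeIn THzReconstruction-class the per-iteration diagnostics list.
setMethod("reconDiagnostics", "THzReconstruction",
          function(object) object@diagnostics)

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask: %d of %d pixels (%.1f%%) on a %d x %d grid, seed %s\n",
              nrow(object@indices), prod(object@shape),
              100 * samplingRate(object), object@shape[1L], object@shape[2L],
              ifelse(is.na(object@seed), "<none>", object@seed)))
})

setMethod("show", "WaveletCoeffs", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("WaveletCoeffs: %s, %d level(s), %d subbands of %d x %d (tight frame)\n",
              object@wavelet, object@levels, d[3L], d[1L], d[2L]))
})

setMethod("show", "ExpCoeffs", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpCoeffs: base a = %g, scale s = %.4g, %d subbands of %d x %d\n",
              object@baseA, object@normScale, d[3L], d[1L], d[2L]))
})

setMethod("show", "PatchGroupSet", function(object) {
  cat(sprintf("PatchGroupSet: %d groups of %d patches (%d x %d, stride %d, window %d) on %d x %d\n",
              nrow(object@refCoords), object@groupSize, object@patchSize,
              object@patchSize, object@stride, object@searchWin,
              object@shape[1L], object@shape[2L]))
  if (object@padCount > 0L)
    cat(sprintf("  %d group(s) padded (window smaller than group size)\n",
                object@padCount))
})

setMethod("show", "GroupCoeffs", function(object) {
  d <- dim(object@values)
  cat(sprintf("GroupCoeffs: %d groups, %d x %d blocks (%s patch / %s similarity transform)\n",
              d[3L], d[1L], d[2L], object@patchTransform,
              object@similarityTransform))
})

setMethod("show", "SolverConfig", function(object) {
  cat("SolverConfig:\n")
  cat(sprintf("  mu = %g, lambda = %g, gamma = %g (%s)\n", object@mu,
              object@lambda, object@gamma,
              if (object@gamma > 0) "hybrid" else "wavelet-only"))
  cat(sprintf("  exponential base a = %g%s, delta = %g, %sweighted\n",
              object@baseA, if (object@baseA == 1) " (identity)" else "",
              object@delta, if (object@weighted) "" else "un"))
  cat(sprintf("  wavelet %s x %d levels; patches L = %d, stride %d, window %d, c = %d, regroup every %d\n",
              object@wavelet, object@levels, object@patchSize, object@stride,
              object@searchWin, object@groupSize, object@regroupInterval))
  cat(sprintf("  maxIter = %d, tol = %g\n", object@maxIter, object@tol))
})

setMethod("show", "THzPhantom", function(object) {
  cat(sprintf("THzPhantom: %d x %d, seed %d, texture amplitude %g\n",
              nrow(object@image), ncol(object@image), object@seed,
              object@params$textureAmplitude))
})

setMethod("show", "THzReconstruction", function(object) {
  d <- object@diagnostics
  cat(sprintf("THzReconstruction: %d x %d image, %d iteration(s)\n",
              nrow(object@image), ncol(object@image), d$iterations))
  if (length(d$dataResidual))
    cat(sprintf("  final relative data residual %.3g, relative change %.3g\n",
                d$dataResidual[length(d$dataResidual)],
                d$relChange[length(d$relChange)]))
})
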