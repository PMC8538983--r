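#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(peakval^2 / MSE)` in decibels, where `peakval` is the
#' maximum value of the reference image (not a fixed bit-depth constant)
#' and MSE the mean squared error. Identical images return `Inf`.
#'
#' @param reference full-scan reference image (matrix).
#' @param estimate reconstructed image of the same shape.
#' @return PSNR in dB (`Inf` for identical images).
#' @examples
#' x <- matrix(runif(64), 8, 8); x[1] <- 1
#' psnr(x, x + 0.1)  # 20 dB when max(x) == 1
#' @export
psnr <- function(reference, estimate) {
  if (!all(dim(reference) == dim(estimate)))
    stop("images must have the same shape")
  mse <- mean((reference - estimate)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(reference)^2 / mse)
}

#' Relative L2 norm error
#'
#' `RLNE = ||x - xhat||_2 / ||x||_2`: 0 iff the images are identical, 1
#' when the estimate is zero (or twice the reference).
#'
#' @inheritParams psnr
#' @return nonnegative scalar.
#' @export
rlne <- function(reference, estimate) {
  if (!all(dim(reference) == dim(estimate)))
    stop("images must have the same shape")
  refNorm <- sqrt(sum(reference^2))
  if (refNorm == 0) stop("RLNE is undefined for an all-zero reference")
  sqrt(sum((reference - estimate)^2)) / refNorm
}
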