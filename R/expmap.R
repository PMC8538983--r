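# Exponential reparameterization of wavelet coefficients and the
# magnitude-inverse weights of the reweighted L1 penalty.

# returns list(values, scale); a == 1 is the identity limit (m itself)
.expMapArr <- function(r, a) {
  s <- max(abs(r))
  if (s == 0 || !is.finite(s)) s <- 1
  m <- abs(r) / s
  v <- if (a == 1) m else (a^m - 1) / (a - 1)
  list(values = sign(r) * v, scale = s)
}

# inverse map; magnitudes beyond 1 are clipped first (returns clip count
# via attribute so callers can log it)
.expInvArr <- function(v, a, s) {
  mag <- abs(v)
  nclip <- sum(mag > 1)
  if (nclip > 0) mag <- pmin(mag, 1)
  r <- if (a == 1) mag else log1p((a - 1) * mag) / log(a)
  out <- sign(v) * r * s
  attr(out, "clipped") <- nclip
  out
}

#' Exponential sparsification of wavelet coefficients
#'
#' Maps coefficient magnitudes, normalized to \[0, 1\] by the global scale
#' `s = max(|r|)`, through the pointwise exponential
#' \eqn{(a^m - 1)/(a - 1)}, preserving signs. For `a > 1` the map is
#' monotone and convex on \[0, 1\], so small coefficients are suppressed
#' relative to large ones, producing a sparser representation. The scale
#' and base are recorded so the map is invertible. `baseA = 1` gives the
#' identity limit (plain normalized magnitudes).
#'
#' @param coeffs a [WaveletCoeffs-class].
#' @param baseA exponent base, >= 1; default 10.
#' @return an [ExpCoeffs-class].
#' @examples
#' w <- swtForward(matrix(rnorm(256), 16, 16), "haar", 1)
#' e <- expMap(w, 10)
#' range(abs(coeffArray(e)))  # within [0, 1]
#' @export
expMap <- function(coeffs, baseA = 10) {
  stopifnot(is(coeffs, "WaveletCoeffs"))
  if (!is.numeric(baseA) || length(baseA) != 1L || baseA < 1)
    stop("baseA must be a single number >= 1")
  if (!all(is.finite(coeffs@coeffs))) stop("non-finite wavelet coefficients")
  m <- .expMapArr(coeffs@coeffs, baseA)
  new("ExpCoeffs", values = m$values, baseA = baseA, normScale = m$scale,
      wavelet = coeffs@wavelet, levels = coeffs@levels)
}

#' Invert the exponential coefficient map
#'
#' Recovers linear-domain wavelet coefficients:
#' \eqn{m = \log_a(1 + (a - 1)|r_e|)}, rescaled by the recorded
#' normalization and with signs reattached. Magnitudes outside \[0, 1\]
#' (which arise when split variables drift during the iteration) are
#' clipped before inversion; the number of clipped entries is reported in
#' the `"clipped"` attribute of the result's coefficient array.
#'
#' @param expcoeffs an [ExpCoeffs-class] (magnitudes may exceed 1; they are
#'   clipped).
#' @return a [WaveletCoeffs-class].
#' @export
expMapInverse <- function(expcoeffs) {
  stopifnot(is(expcoeffs, "ExpCoeffs"))
  r <- .expInvArr(expcoeffs@values, expcoeffs@baseA, expcoeffs@normScale)
  co <- array(as.numeric(r), dim = dim(expcoeffs@values))
  attr(co, "clipped") <- attr(r, "clipped")
  new("WaveletCoeffs", coeffs = co, wavelet = expcoeffs@wavelet,
      levels = expcoeffs@levels)
}

#' Magnitude-inverse weights for the reweighted L1 penalty
#'
#' Computes \eqn{w_n = 1/(|r_{e,n}| + \delta)} on the normalized
#' exponential magnitudes (clipped to \[0, 1\]), so weights are inversely
#' proportional to the current coefficient magnitudes: large coefficients
#' are penalized lightly, near-zero ones heavily, approximating L0
#' behavior. All weights lie in \eqn{[1/(1+\delta), 1/\delta]}.
#'
#' @param expcoeffs an [ExpCoeffs-class] (or a bare numeric array of
#'   normalized magnitudes).
#' @param delta positive stabilizer; default 1e-5, small enough not to
#'   affect the results.
#' @return numeric array of weights with the coefficient layout.
#' @export
computeWeights <- function(expcoeffs, delta = 1e-5) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  v <- if (is(expcoeffs, "ExpCoeffs")) expcoeffs@values else expcoeffs
  1 / (pmin(abs(v), 1) + delta)
}
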