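# Shift-invariant (undecimated) wavelet tight frame.
#
# The a-trous decomposition is evaluated in the Fourier domain: circular
# convolution by the level-j filters (taps upsampled by 2^(j-1)) is an
# elementwise product with their frequency response. Each level splits the
# running approximation into four subbands with a scalar 1/2, which makes
# every split an isometry for conjugate-quadrature filter pairs
# (|H|^2 + |G|^2 = 2 pointwise), hence the whole frame tight: Psi^T Psi = I.
# Boundary handling is periodic, which keeps tightness exact.

.waveletFilters <- function(name) {
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604),
    db4 = c(0.2303778133088964, 0.7148465705529154, 0.6308807679298587,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690),
    stop("unsupported wavelet family: ", name))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)  # conjugate quadrature mirror
  list(lo = lo, hi = hi)
}

# frequency response of taps upsampled by `up`, at the n DFT frequencies
.filterHat <- function(taps, n, up) {
  k <- (seq_along(taps) - 1) * up
  as.vector(exp(-2i * pi * outer(0:(n - 1), k) / n) %*% taps)
}

# per-level 2-D frequency-domain multipliers for a given image shape
.swtPlan <- function(shape, wavelet, levels) {
  f <- .waveletFilters(wavelet)
  lapply(seq_len(levels), function(j) {
    up <- 2L^(j - 1L)
    H1 <- .filterHat(f$lo, shape[1L], up); G1 <- .filterHat(f$hi, shape[1L], up)
    H2 <- .filterHat(f$lo, shape[2L], up); G2 <- .filterHat(f$hi, shape[2L], up)
    list(LH = 0.5 * outer(H1, G2), HL = 0.5 * outer(G1, H2),
         HH = 0.5 * outer(G1, G2), LL = 0.5 * outer(H1, H2))
  })
}

.checkLevels <- function(shape, levels) {
  if (levels < 1L || levels > floor(log2(min(shape))))
    stop("levels must be between 1 and log2(min(image dimension)) = ",
         floor(log2(min(shape))))
}

.swtForwardArr <- function(x, plan) {
  J <- length(plan)
  n1 <- nrow(x); n2 <- ncol(x); np <- n1 * n2
  out <- array(0, c(n1, n2, 3L * J + 1L))
  xh <- stats::fft(x)
  s <- 1L
  for (j in seq_len(J)) {
    p <- plan[[j]]
    out[, , s]      <- Re(stats::fft(xh * p$LH, inverse = TRUE)) / np
    out[, , s + 1L] <- Re(stats::fft(xh * p$HL, inverse = TRUE)) / np
    out[, , s + 2L] <- Re(stats::fft(xh * p$HH, inverse = TRUE)) / np
    xh <- xh * p$LL
    s <- s + 3L
  }
  out[, , 3L * J + 1L] <- Re(stats::fft(xh, inverse = TRUE)) / np
  out
}

.swtAdjointArr <- function(co, plan) {
  J <- length(plan)
  n1 <- dim(co)[1L]; n2 <- dim(co)[2L]; np <- n1 * n2
  acc <- stats::fft(co[, , 3L * J + 1L])
  for (j in rev(seq_len(J))) {
    p <- plan[[j]]
    s <- 3L * (j - 1L) + 1L
    acc <- acc * Conj(p$LL) +
      stats::fft(co[, , s])      * Conj(p$LH) +
      stats::fft(co[, , s + 1L]) * Conj(p$HL) +
      stats::fft(co[, , s + 2L]) * Conj(p$HH)
  }
  Re(stats::fft(acc, inverse = TRUE)) / np
}

.subbandNames <- function(levels) {
  c(as.vector(t(outer(seq_len(levels), c("LH", "HL", "HH"),
                      function(j, b) paste0(b, j)))), "LL")
}

#' Undecimated wavelet analysis (tight frame)
#'
#' Multilevel shift-invariant (stationary) wavelet decomposition with
#' periodic boundary handling, scaled so the frame is tight:
#' `swtAdjoint(swtForward(x)) == x` and coefficient energy equals image
#' energy (Parseval).
#'
#' @param image 2-D numeric matrix with finite values.
#' @param wavelet filter family: "haar", "db2" (default) or "db4".
#' @param levels decomposition depth; at most `log2(min(dim(image)))`.
#' @return a [WaveletCoeffs-class] holding `3 * levels + 1` full-size
#'   subbands (details LH/HL/HH per level, coarsest approximation last).
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' w <- swtForward(x, "db2", 2)
#' max(abs(swtAdjoint(w) - x))  # ~1e-16
#' @export
swtForward <- function(image, wavelet = "db2", levels = 3L) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  levels <- as.integer(levels)
  .checkLevels(dim(image), levels)
  plan <- .swtPlan(dim(image), wavelet, levels)
  co <- .swtForwardArr(image, plan)
  dimnames(co) <- list(NULL, NULL, .subbandNames(levels))
  new("WaveletCoeffs", coeffs = co, wavelet = wavelet, levels = levels)
}

#' Undecimated wavelet adjoint (synthesis)
#'
#' Exact adjoint of [swtForward()]. Because the frame is tight it is also
#' the inverse: applying it to unmodified analysis coefficients returns the
#' original image to machine precision.
#'
#' @param coeffs a [WaveletCoeffs-class].
#' @return numeric image matrix.
#' @export
swtAdjoint <- function(coeffs) {
  stopifnot(is(coeffs, "WaveletCoeffs"))
  plan <- .swtPlan(dim(coeffs@coeffs)[1:2], coeffs@wavelet, coeffs@levels)
  .swtAdjointArr(coeffs@coeffs, plan)
}
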