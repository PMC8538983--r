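#' Synthetic seed-like phantom
#'
#' Generates a deterministic test object emulating a raster-scanned grain
#' seed: a rotated bright ellipse (plateau ~0.7) with smooth low-frequency
#' internal variation, band-limited random texture, and a thin dark crease
#' line along the major axis, on a dark background (~0.05) with a sharp
#' object boundary. Most spectral energy sits in the low-frequency band,
#' so the phantom is strongly wavelet-compressible, like the smooth
#' low-frequency-dominant objects the reconstruction targets.
#'
#' @param shape integer(2), at least 32 x 32.
#' @param seed integer seed; the phantom is reproducible given the seed
#'   (the global RNG state is left untouched).
#' @param textureAmplitude RMS amplitude of the band-limited internal
#'   texture (default 0.08; 0 gives a piecewise-smooth object).
#' @return a [THzPhantom-class].
#' @examples
#' ph <- seedPhantom(c(64, 64), seed = 1)
#' range(phantomImage(ph))
#' @export
seedPhantom <- function(shape = c(64, 64), seed = 1L,
                        textureAmplitude = 0.08) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("phantom shape must be at least 32 x 32")
  n1 <- shape[1L]; n2 <- shape[2L]
  bg <- 0.05; plateau <- 0.7; angle <- 25 * pi / 180
  axes <- c(0.62, 0.42)  # semi-axes in normalized units
  u <- matrix(rep(seq(-1, 1, length.out = n1), n2), n1, n2)
  v <- matrix(rep(seq(-1, 1, length.out = n2), each = n1), n1, n2)
  ur <- cos(angle) * u + sin(angle) * v
  vr <- -sin(angle) * u + cos(angle) * v
  inside <- (ur / axes[1L])^2 + (vr / axes[2L])^2 <= 1
  img <- matrix(bg, n1, n2)
  lowfreq <- 0.06 * sin(1.7 * pi * ur + 1.1) + 0.05 * cos(2.3 * pi * vr - 0.4)
  img[inside] <- plateau + lowfreq[inside]
  if (textureAmplitude > 0) {
    noise <- .withSeed(seed, matrix(stats::rnorm(n1 * n2), n1, n2))
    f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
    f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
    rad <- sqrt(outer(f1^2, f2^2, "+"))
    band <- rad >= 6 / max(n1, n2) & rad <= 14 / max(n1, n2)
    tex <- Re(stats::fft(stats::fft(noise) * band, inverse = TRUE)) / (n1 * n2)
    rms <- sqrt(mean(tex[inside]^2))
    if (rms > 0) tex <- tex * (textureAmplitude / rms)
    img[inside] <- img[inside] + tex[inside]
  }
  crease <- inside & abs(vr) < 0.035 & abs(ur) < 0.55
  img[crease] <- img[crease] - 0.25
  img <- pmin(pmax(img, 0), 1)
  new("THzPhantom", image = img,
      params = list(background = bg, plateau = plateau, angle = angle,
                    axes = axes, textureAmplitude = textureAmplitude),
      seed = as.integer(seed))
}
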