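#' Draw a random sampling mask
#'
#' Selects `M = max(1, floor(rate * N))` distinct pixel positions uniformly
#' at random (without replacement) from an `shape[1] x shape[2]` grid,
#' emulating a raster scan that visits only a random subset of pixels. The
#' selected coordinates are stored in canonical raster order (row-major),
#' so the mask is reproducible byte-for-byte given the seed.
#'
#' @param shape integer(2), image grid dimensions (rows, cols).
#' @param rate sampling fraction in (0, 1].
#' @param seed integer seed for the draw. The global RNG state is left
#'   untouched.
#' @return a [SamplingMask-class].
#' @examples
#' m <- randomMask(c(10, 10), 0.2, seed = 1)
#' nrow(maskIndices(m))  # 20
#' @export
randomMask <- function(shape, rate, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be two positive integers")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1)
    stop("rate must be a single number in (0, 1]")
  n <- prod(shape)
  m <- max(1L, as.integer(floor(rate * n)))
  lin <- sort(.withSeed(seed, sample.int(n, m)))
  # column-major linear index -> (row, col); sorting linear indices gives
  # column-major order, so reorder to raster (row-major) order
  rows <- ((lin - 1L) %% shape[1L]) + 1L
  cols <- ((lin - 1L) %/% shape[1L]) + 1L
  o <- order(rows, cols)
  new("SamplingMask", shape = shape,
      indices = cbind(row = rows[o], col = cols[o]),
      rate = rate, seed = as.integer(seed))
}

#' Construct a mask from explicit coordinates
#'
#' @param shape integer(2) grid dimensions.
#' @param indices M x 2 matrix of 1-based (row, col) coordinates.
#' @param seed optional seed to record for provenance.
#' @return a [SamplingMask-class]; coordinates are reordered to canonical
#'   raster order.
#' @export
maskFromIndices <- function(shape, indices, seed = NA_integer_) {
  indices <- matrix(as.integer(indices), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  o <- order(indices[, 1L], indices[, 2L])
  indices <- indices[o, , drop = FALSE]
  new("SamplingMask", shape = as.integer(shape), indices = indices,
      rate = nrow(indices) / prod(shape), seed = as.integer(seed))
}

# linear (column-major) pixel indices of the sampled positions
.maskLinear <- function(mask) {
  (mask@indices[, 2L] - 1L) * mask@shape[1L] + mask@indices[, 1L]
}

#' Apply the measurement operator
#'
#' Computes `y = R x`: reads the image values at the mask coordinates, in
#' mask order.
#'
#' @param image numeric matrix with the mask's grid shape.
#' @param mask a [SamplingMask-class].
#' @return numeric vector of length M.
#' @export
measure <- function(image, mask) {
  if (!is.matrix(image) || !all(dim(image) == mask@shape))
    stop("image shape does not match the mask grid")
  as.numeric(image[.maskLinear(mask)])
}

#' Apply the adjoint of the measurement operator
#'
#' Computes `R^T y`: scatters the measurement vector back onto a zero image
#' at the mask coordinates. Because each pixel is sampled at most once,
#' `R R^T = I` and `R^T R` is a 0/1 diagonal.
#'
#' @param y numeric vector of length M (mask order).
#' @param mask a [SamplingMask-class].
#' @return numeric matrix of the mask's grid shape.
#' @export
maskAdjoint <- function(y, mask) {
  if (length(y) != nrow(mask@indices))
    stop("measurement length does not match the mask")
  img <- matrix(0, mask@shape[1L], mask@shape[2L])
  img[.maskLinear(mask)] <- y
  img
}

#' Dense 0/1 indicator image of a mask
#'
#' @param mask a [SamplingMask-class].
#' @return numeric matrix with 1 at sampled pixels, 0 elsewhere (the
#'   diagonal of `R^T R`).
#' @export
maskIndicator <- function(mask) {
  maskAdjoint(rep(1, nrow(mask@indices)), mask)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
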