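#' @import methods
NULL

#' Random pixel-subsampling mask
#'
#' Represents the row-selection measurement matrix \eqn{R} of a sparse
#' raster scan: an ordered set of \eqn{M} distinct pixel coordinates out of
#' the \eqn{N} pixels of an image grid. Each row of \eqn{R} has a single
#' entry equal to 1 at a measured pixel, so \eqn{R} is never materialized as
#' a dense matrix; only the coordinate list is stored.
#'
#' @slot shape integer(2), image grid dimensions (rows, cols).
#' @slot indices integer matrix with \eqn{M} rows and columns (row, col),
#'   1-based, in canonical raster order (row-major). File formats use
#'   0-based coordinates; see [writeMask()].
#' @slot rate numeric(1), nominal sampling fraction in (0, 1].
#' @slot seed integer(1), RNG seed used to draw the mask (NA when the mask
#'   was loaded or constructed explicitly).
#'
#' @seealso [randomMask()], [measure()], [maskAdjoint()]
#' @export
setClass("SamplingMask",
  representation(shape = "integer", indices = "matrix",
                 rate = "numeric", seed = "integer"))

setValidity("SamplingMask", function(object) {
  s <- object@shape
  idx <- object@indices
  if (length(s) != 2L || any(s < 1L)) return("shape must be two positive integers")
  if (!is.numeric(idx) || ncol(idx) != 2L) return("indices must be an M x 2 matrix")
  if (nrow(idx) < 1L) return("mask must contain at least one pixel")
  if (any(idx < 1L) || any(idx[, 1L] > s[1L]) || any(idx[, 2L] > s[2L]))
    return("indices out of the image grid")
  lin <- (idx[, 2L] - 1L) * s[1L] + idx[, 1L]
  if (anyDuplicated(lin)) return("indices must be distinct")
  if (length(object@rate) != 1L || object@rate <= 0 || object@rate > 1)
    return("rate must be in (0, 1]")
  TRUE
})

#' Undecimated wavelet coefficients
#'
#' Coefficients of the shift-invariant (stationary/undecimated) wavelet
#' analysis \eqn{r = \Psi x}. The transform is scaled to a tight frame
#' (\eqn{\Psi^T \Psi = I}), so every subband has the shape of the image and
#' the adjoint inverts the analysis exactly.
#'
#' @slot coeffs numeric array, rows x cols x (3*levels + 1); subbands are
#'   ordered LH1, HL1, HH1, LH2, ..., HHJ, LL (coarsest approximation last).
#' @slot wavelet character(1), filter family ("haar", "db2", "db4").
#' @slot levels integer(1), number of decomposition levels.
#'
#' @seealso [swtForward()], [swtAdjoint()]
#' @export
setClass("WaveletCoeffs",
  representation(coeffs = "array", wavelet = "character", levels = "integer"))

setValidity("WaveletCoeffs", function(object) {
  d <- dim(object@coeffs)
  if (length(d) != 3L) return("coeffs must be a 3-D array")
  if (d[3L] != 3L * object@levels + 1L)
    return("coeffs must hold 3*levels + 1 subbands")
  if (object@levels < 1L) return("levels must be >= 1")
  TRUE
})

#' Exponentially reparameterized wavelet coefficients
#'
#' Wavelet coefficients after the sparsity-enhancing exponential map
#' \eqn{(a^m - 1)/(a - 1)} applied to magnitudes normalized to \[0, 1\] by a
#' recorded global scale, signs preserved. \code{baseA = 1} denotes the
#' identity limit of the map (used by the single-sparse-constraint
#' baseline).
#'
#' @slot values signed numeric array, same layout as the underlying
#'   [WaveletCoeffs-class] coefficients; magnitudes lie in the unit interval.
#' @slot baseA numeric(1), exponent base \eqn{a \ge 1}.
#' @slot normScale numeric(1), the positive scale \eqn{s = \max|r|} used for
#'   normalization (1 when all coefficients are zero or in identity mode).
#' @slot wavelet,levels transform descriptor copied from the source
#'   coefficients.
#'
#' @seealso [expMap()], [expMapInverse()], [computeWeights()]
#' @export
setClass("ExpCoeffs",
  representation(values = "array", baseA = "numeric", normScale = "numeric",
                 wavelet = "character", levels = "integer"))

setValidity("ExpCoeffs", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
  if (object@baseA < 1) return("baseA must be >= 1")
  if (object@normScale <= 0) return("normScale must be positive")
  if (max(abs(object@values)) > 1 + 1e-9)
    return("magnitudes must lie in the unit interval")
  TRUE
})

#' Block-matched patch groups
#'
#' For every reference patch on a stride grid, the coordinates of its
#' \eqn{c} best-matched patches (Euclidean distance within a local search
#' window, reference first). Together with the separable orthonormal 3-D
#' transform, this defines the nonlocal self-similarity operators
#' \eqn{\Psi_p^{3D}}. The object precomputes the pixel gather/scatter index
#' and the per-pixel coverage counts the solver needs.
#'
#' @slot shape integer(2), image dimensions.
#' @slot patchSize,stride,searchWin,groupSize integer(1): patch side L,
#'   reference-grid stride, search window side T, group size c.
#' @slot refCoords integer P x 2 matrix of 1-based top-left reference
#'   coordinates, raster order.
#' @slot memberRows,memberCols integer c x P matrices of member top-left
#'   coordinates (column p lists the members of group p, reference first).
#' @slot pixelIndex integer L^2 x (P*c) matrix of linear pixel indices for
#'   gathering member patches (member fastest within group).
#' @slot scatterKey,scatterLevels internal precomputation for the adjoint
#'   scatter-add.
#' @slot coverage numeric image of per-pixel patch coverage counts (the
#'   diagonal of \eqn{\sum_p (\Psi_p^{3D})^T \Psi_p^{3D}}).
#' @slot padCount integer(1), number of groups padded because the window
#'   held fewer than c candidates (only possible on tiny images).
#'
#' @seealso [buildPatchGroups()], [groupForward()], [groupAdjoint()],
#'   [coverageDiagonal()]
#' @export
setClass("PatchGroupSet",
  representation(shape = "integer", patchSize = "integer", stride = "integer",
                 searchWin = "integer", groupSize = "integer",
                 refCoords = "matrix", memberRows = "matrix",
                 memberCols = "matrix", pixelIndex = "matrix",
                 scatterKey = "integer", scatterLevels = "integer",
                 coverage = "matrix", padCount = "integer"))

setValidity("PatchGroupSet", function(object) {
  L <- object@patchSize
  P <- nrow(object@refCoords)
  cgs <- object@groupSize
  if (ncol(object@memberRows) != P || ncol(object@memberCols) != P)
    return("member coordinate matrices must have one column per group")
  if (nrow(object@memberRows) != cgs || nrow(object@memberCols) != cgs)
    return("member coordinate matrices must have groupSize rows")
  if (any(object@memberRows < 1L) ||
      any(object@memberRows > object@shape[1L] - L + 1L) ||
      any(object@memberCols < 1L) ||
      any(object@memberCols > object@shape[2L] - L + 1L))
    return("member patches must lie fully inside the image")
  if (any(object@memberRows[1L, ] != object@refCoords[, 1L]) ||
      any(object@memberCols[1L, ] != object@refCoords[, 2L]))
    return("each reference patch must be the first member of its group")
  TRUE
})

#' 3-D transform coefficients of patch groups
#'
#' Coefficient blocks \eqn{\Theta_p} of the separable orthonormal 3-D
#' transform (2-D transform over each L x L patch face, 1-D transform along
#' the similarity axis) applied to every block-matched patch group. The
#' transform is orthonormal, so the energy of each block equals the energy
#' of the stacked patches.
#'
#' @slot values numeric array, L^2 x c x P.
#' @slot patchTransform,similarityTransform character(1) descriptors
#'   ("dct" or "haar").
#'
#' @seealso [groupForward()], [groupAdjoint()]
#' @export
setClass("GroupCoeffs",
  representation(values = "array", patchTransform = "character",
                 similarityTransform = "character"))

setValidity("GroupCoeffs", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be L^2 x c x P")
  TRUE
})

#' Solver configuration
#'
#' All tunable parameters of the split Bregman reconstruction. The defaults
#' were set empirically on the synthetic seed phantom; see the package
#' vignette for the rationale behind each value.
#'
#' @slot mu numeric(1), data-fidelity weight (> 0).
#' @slot lambda numeric(1), wavelet-sparsity split weight (> 0); the
#'   shrinkage threshold of the wavelet subproblem is weights/lambda.
#' @slot gamma numeric(1), nonlocal split weight (>= 0); 0 disables the
#'   nonlocal prior (single-sparse-constraint mode).
#' @slot baseA numeric(1), exponential map base (>= 1; 1 = identity map).
#' @slot delta numeric(1), reweighting stabilizer (> 0).
#' @slot weighted logical(1), whether the wavelet penalty is iteratively
#'   reweighted.
#' @slot wavelet character(1), wavelet family; \code{levels} integer(1),
#'   decomposition depth.
#' @slot levels,patchSize,stride,searchWin,groupSize,regroupInterval,maxIter
#'   integer(1) counterparts of L, stride, T, c, J, and the iteration cap.
#' @slot tol numeric(1), relative-change stopping threshold (> 0).
#' @slot seed integer(1), recorded seed for provenance (the solver itself
#'   is deterministic).
#'
#' @seealso [solverConfig()], [sscConfig()], [reconstructHSM()]
#' @export
setClass("SolverConfig",
  representation(mu = "numeric", lambda = "numeric", gamma = "numeric",
                 baseA = "numeric", delta = "numeric", weighted = "logical",
                 wavelet = "character", levels = "integer",
                 patchSize = "integer", stride = "integer",
                 searchWin = "integer", groupSize = "integer",
                 regroupInterval = "integer", maxIter = "integer",
                 tol = "numeric", seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (object@mu <= 0) return("mu must be > 0")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@gamma < 0) return("gamma must be >= 0")
  if (object@baseA < 1) return("baseA must be >= 1")
  if (object@delta <= 0) return("delta must be > 0")
  if (object@tol <= 0) return("tol must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@patchSize < 1L || object@stride < 1L || object@groupSize < 1L)
    return("patchSize, stride and groupSize must be >= 1")
  if (object@regroupInterval < 1L) return("regroupInterval must be >= 1")
  TRUE
})

#' Synthetic seed-like phantom
#'
#' A deterministic synthetic test object emulating a raster-scanned grain
#' seed: a smooth bright rotated ellipse with internal low-frequency
#' variation, band-limited texture and a thin crease line, on a dark
#' background, with a sharp boundary. Values lie in the unit interval.
#'
#' @slot image numeric matrix in the unit interval.
#' @slot params named list describing the components (background level,
#'   ellipse geometry, texture amplitude, ...).
#' @slot seed integer(1) RNG seed; the phantom is reproducible given the
#'   seed.
#'
#' @seealso [seedPhantom()]
#' @export
setClass("THzPhantom",
  representation(image = "matrix", params = "list", seed = "integer"))

setValidity("THzPhantom", function(object) {
  if (min(object@image) < 0 || max(object@image) > 1)
    return("phantom values must lie in the unit interval")
  TRUE
})

#' Reconstruction result
#'
#' The output of [reconstructHSM()] / [reconstructSSC()]: the reconstructed
#' image together with per-iteration diagnostics (data residual, split
#' constraint residuals, relative change, objective surrogate) and an echo
#' of the configuration used.
#'
#' @slot image numeric matrix, the reconstructed image.
#' @slot diagnostics named list of per-iteration traces and counters.
#' @slot config the [SolverConfig-class] used.
#'
#' @seealso [reconstructHSM()], [reconImage()], [reconDiagnostics()]
#' @export
setClass("THzReconstruction",
  representation(image = "matrix", diagnostics = "list",
                 config = "SolverConfig"))
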