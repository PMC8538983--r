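# Nonlocal self-similarity: patch grid, block matching, and the separable
# orthonormal 3-D transform over stacked patch groups. Because the 3-D
# transform is orthonormal, the normal operator sum_p (Psi_p^3D)^T Psi_p^3D
# is diagonal, equal to the per-pixel patch coverage count -- which is what
# makes the solver's quadratic subproblem an exact elementwise division.

# orthonormal DCT-II matrix (rows = frequencies)
.dctMatrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  D[1L, ] <- sqrt(1 / n)
  D
}

# orthonormal Haar matrix for n a power of two
.haarMatrix <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) {
    H <- rbind(kronecker(H, matrix(c(1, 1), 1, 2)),
               kronecker(diag(nrow(H)), matrix(c(1, -1), 1, 2)))
  }
  H / sqrt(rowSums(H^2))
}

.isPow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

# 1-D transform along the similarity axis: Haar when c is a power of two,
# orthonormal DCT otherwise
.similarityMatrix <- function(c) {
  if (.isPow2(c)) list(M = .haarMatrix(c), name = "haar")
  else list(M = .dctMatrix(c), name = "dct")
}

#' Reference patch grid
#'
#' Top-left coordinates of the reference patches: starts at 1 with the
#' given stride along each axis, and the final start clamped to
#' `shape - L + 1` so the image borders are always covered.
#'
#' @param shape integer(2) image dimensions.
#' @param L patch side length (default 8).
#' @param stride grid step (default 4).
#' @return integer P x 2 matrix of 1-based (row, col) top-left coordinates
#'   in raster order.
#' @examples
#' extractPatchGrid(c(12, 12), 8, 4)  # starts {1, 5} per axis, 4 patches
#' @export
extractPatchGrid <- function(shape, L = 8L, stride = 4L) {
  shape <- as.integer(shape); L <- as.integer(L); stride <- as.integer(stride)
  if (L > min(shape)) stop("patch size exceeds the image")
  if (stride < 1L) stop("stride must be >= 1")
  starts <- function(n) {
    s <- seq.int(1L, n - L + 1L, by = stride)
    if (s[length(s)] != n - L + 1L) s <- c(s, n - L + 1L)
    s
  }
  rs <- starts(shape[1L]); cs <- starts(shape[2L])
  cbind(row = rep(rs, each = length(cs)), col = rep(cs, times = length(rs)))
}

# window of candidate top-left positions for a reference patch: the T x T
# window centered on the patch, clipped to the image; candidates are all
# positions whose patch lies fully inside the clipped window
.candidateRange <- function(r0, n, L, Tw) {
  w0 <- max(1L, r0 + L %/% 2L - Tw %/% 2L)
  w1 <- min(n, w0 + Tw - 1L)
  w0 <- max(1L, w1 - Tw + 1L)  # keep the clipped window as large as possible
  c(max(1L, w0), min(n - L + 1L, w1 - L + 1L))
}

#' Block matching for a single reference patch
#'
#' Finds the `c` patches most similar (squared Euclidean distance) to the
#' reference patch among all patch positions fully inside the `T x T`
#' search window centered on it (clipped at image borders, candidate
#' stride 1). The reference is always first; ties are broken by raster
#' order of the candidate coordinate. If the window holds fewer than `c`
#' candidates the last one is repeated.
#'
#' @param image numeric matrix.
#' @param refCoord integer(2), 1-based top-left (row, col) of the reference
#'   patch.
#' @param L patch side; `Tw` search window side; `c` group size.
#' @param Tw,c see above.
#' @return integer c x 2 matrix of member top-left coordinates, reference
#'   first.
#' @export
blockMatch <- function(image, refCoord, L = 8L, Tw = 40L, c = 10L) {
  n1 <- nrow(image); n2 <- ncol(image)
  r0 <- as.integer(refCoord[1L]); c0 <- as.integer(refCoord[2L])
  if (r0 < 1L || c0 < 1L || r0 + L - 1L > n1 || c0 + L - 1L > n2)
    stop("reference patch outside the image")
  rr <- .candidateRange(r0, n1, L, Tw)
  cr <- .candidateRange(c0, n2, L, Tw)
  ref <- as.vector(image[r0:(r0 + L - 1L), c0:(c0 + L - 1L)])
  cand <- cbind(row = rep(rr[1L]:rr[2L], each = cr[2L] - cr[1L] + 1L),
                col = rep(cr[1L]:cr[2L], times = rr[2L] - rr[1L] + 1L))
  d2 <- vapply(seq_len(nrow(cand)), function(k) {
    p <- image[cand[k, 1L]:(cand[k, 1L] + L - 1L),
               cand[k, 2L]:(cand[k, 2L] + L - 1L)]
    sum((as.vector(p) - ref)^2)
  }, numeric(1))
  isRef <- cand[, 1L] == r0 & cand[, 2L] == c0
  ord <- order(d2, seq_len(nrow(cand)))
  ord <- ord[!isRef[ord]]
  take <- utils::head(ord, c - 1L)
  if (length(take) < c - 1L && length(take) > 0L)
    take <- c(take, rep(take[length(take)], c - 1L - length(take)))
  if (length(take) == 0L) take <- rep(which(isRef), c - 1L)
  rbind(c(r0, c0), cand[take, , drop = FALSE])
}

#' Build the patch group set for an image
#'
#' Runs block matching for every reference patch on the stride grid and
#' precomputes the gather/scatter pixel index and per-pixel coverage
#' counts used by [groupForward()] and [groupAdjoint()]. The candidate
#' ranking is computed with one BLAS cross-product over all patches, but
#' is identical to per-reference [blockMatch()].
#'
#' @param image numeric matrix.
#' @param L patch side (default 8); `stride` reference grid step (default
#'   4); `Tw` search window side (default 40); `c` group size (default 10).
#' @param stride,Tw,c see above.
#' @return a [PatchGroupSet-class].
#' @export
buildPatchGroups <- function(image, L = 8L, stride = 4L, Tw = 40L, c = 10L) {
  n1 <- nrow(image); n2 <- ncol(image)
  L <- as.integer(L); stride <- as.integer(stride)
  Tw <- as.integer(Tw); cgs <- as.integer(c)
  refs <- extractPatchGrid(c(n1, n2), L, stride)
  P <- nrow(refs)
  nAr <- n1 - L + 1L; nAc <- n2 - L + 1L
  # all patch positions, raster order (col fastest): p = (ar-1)*nAc + ac
  ar <- rep(seq_len(nAr), each = nAc)
  ac <- rep(seq_len(nAc), times = nAr)
  base <- (ac - 1L) * n1 + ar
  off <- as.vector(outer(0:(L - 1L), (0:(L - 1L)) * n1, "+"))
  allIdx <- outer(off, base, "+")               # L^2 x nA
  Pall <- matrix(image[allIdx], nrow = L * L)
  cn2 <- colSums(Pall * Pall)
  refP <- (refs[, 1L] - 1L) * nAc + refs[, 2L]
  crossAll <- crossprod(Pall, Pall[, refP, drop = FALSE])  # nA x P
  memberP <- matrix(0L, cgs, P)
  pad <- 0L
  for (p in seq_len(P)) {
    rr <- .candidateRange(refs[p, 1L], n1, L, Tw)
    cr <- .candidateRange(refs[p, 2L], n2, L, Tw)
    ai <- rr[1L]:rr[2L]; aj <- cr[1L]:cr[2L]
    cand <- as.vector(t(outer((ai - 1L) * nAc, aj, "+")))  # raster order
    d2 <- cn2[cand] - 2 * crossAll[cand, p] + cn2[refP[p]]
    ord <- order(d2, seq_along(cand))
    ord <- ord[cand[ord] != refP[p]]
    take <- utils::head(cand[ord], cgs - 1L)
    if (length(take) < cgs - 1L) {
      pad <- pad + 1L
      fill <- if (length(take)) take[length(take)] else refP[p]
      take <- c(take, rep(fill, cgs - 1L - length(take)))
    }
    memberP[, p] <- c(refP[p], take)
  }
  mRows <- matrix(((memberP - 1L) %/% nAc) + 1L, cgs, P)
  mCols <- matrix(((memberP - 1L) %% nAc) + 1L, cgs, P)
  pixelIndex <- allIdx[, as.vector(memberP), drop = FALSE]  # L^2 x (P*c)
  iv <- as.vector(pixelIndex)
  lev <- sort(unique(iv))
  key <- match(iv, lev)
  cov <- matrix(0, n1, n2)
  cov[lev] <- as.vector(rowsum(rep(1, length(key)), key))
  new("PatchGroupSet", shape = c(n1, n2), patchSize = L, stride = stride,
      searchWin = Tw, groupSize = cgs, refCoords = refs,
      memberRows = mRows, memberCols = mCols, pixelIndex = pixelIndex,
      scatterKey = as.integer(key), scatterLevels = as.integer(lev),
      coverage = cov, padCount = pad)
}

# cached transform matrices for a group set
.groupTransforms <- function(groups) {
  L <- groups@patchSize
  D <- .dctMatrix(L)
  K2 <- kronecker(D, D)  # 2-D DCT on vec'd patch faces (column-major vec)
  sim <- .similarityMatrix(groups@groupSize)
  list(K2 = K2, Dc = sim$M, simName = sim$name)
}

.groupForwardArr <- function(image, groups, tr) {
  L2 <- groups@patchSize^2
  cgs <- groups@groupSize
  P <- nrow(groups@refCoords)
  X <- matrix(image[groups@pixelIndex], nrow = L2)      # L^2 x (P*c)
  F2 <- tr$K2 %*% X
  A <- aperm(array(F2, c(L2, cgs, P)), c(2L, 1L, 3L))   # c x L^2 x P
  F3 <- tr$Dc %*% matrix(A, nrow = cgs)
  aperm(array(F3, c(cgs, L2, P)), c(2L, 1L, 3L))        # L^2 x c x P
}

.groupAdjointArr <- function(values, groups, tr) {
  L2 <- groups@patchSize^2
  cgs <- groups@groupSize
  P <- nrow(groups@refCoords)
  A <- aperm(values, c(2L, 1L, 3L))                     # c x L^2 x P
  B <- crossprod(tr$Dc, matrix(A, nrow = cgs))
  X <- crossprod(tr$K2, matrix(aperm(array(B, c(cgs, L2, P)),
                                     c(2L, 1L, 3L)), nrow = L2))
  sums <- rowsum(as.vector(X), groups@scatterKey)
  img <- matrix(0, groups@shape[1L], groups@shape[2L])
  img[groups@scatterLevels] <- as.vector(sums)
  img
}

#' Grouped 3-D transform (forward)
#'
#' Stacks each group's member patches into an `L x L x c` block and applies
#' the separable orthonormal 3-D transform: a 2-D DCT on each patch face
#' followed by a 1-D orthonormal transform (Haar when `c` is a power of
#' two, DCT otherwise) along the similarity axis. Orthonormality preserves
#' each block's energy.
#'
#' @param image numeric matrix.
#' @param groups a [PatchGroupSet-class] built for the same shape.
#' @return a [GroupCoeffs-class] with values of dimension L^2 x c x P.
#' @export
groupForward <- function(image, groups) {
  stopifnot(is(groups, "PatchGroupSet"))
  if (!all(dim(image) == groups@shape)) stop("image shape does not match groups")
  tr <- .groupTransforms(groups)
  new("GroupCoeffs", values = .groupForwardArr(image, groups, tr),
      patchTransform = "dct", similarityTransform = tr$simName)
}

#' Grouped 3-D transform (adjoint)
#'
#' Inverse-transforms every coefficient block and scatter-adds the member
#' patches back to their image locations: the exact adjoint of
#' [groupForward()]. The normal operator `groupAdjoint(groupForward(x))`
#' equals the elementwise product of `x` with [coverageDiagonal()].
#'
#' @param coeffs a [GroupCoeffs-class] (or bare L^2 x c x P array).
#' @param groups the [PatchGroupSet-class] the coefficients belong to.
#' @return numeric image matrix.
#' @export
groupAdjoint <- function(coeffs, groups) {
  stopifnot(is(groups, "PatchGroupSet"))
  v <- if (is(coeffs, "GroupCoeffs")) coeffs@values else coeffs
  if (!all(dim(v) == c(groups@patchSize^2, groups@groupSize,
                       nrow(groups@refCoords))))
    stop("coefficient layout does not match groups")
  .groupAdjointArr(v, groups, .groupTransforms(groups))
}

#' Per-pixel patch coverage counts
#'
#' For each pixel, the number of (group, member) patches covering it. This
#' is the diagonal of the nonlocal normal operator
#' \eqn{\sum_p (\Psi_p^{3D})^T \Psi_p^{3D}}, which is diagonal because the
#' 3-D transform is orthonormal.
#'
#' @param groups a [PatchGroupSet-class].
#' @return numeric matrix of integer counts with the image shape.
#' @export
coverageDiagonal <- function(groups) {
  stopifnot(is(groups, "PatchGroupSet"))
  groups@coverage
}
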