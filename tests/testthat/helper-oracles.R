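# Independent oracle implementations used across the test files. These
# deliberately take the slow, literal route (explicit loops, dense
# matrices, grid searches) so they share no code path with the package.

# -- naive undecimated wavelet transform (time-domain circular convolution)

oracleFilters <- function(name) {
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604))
  list(lo = lo, hi = rev(lo) * (-1)^(seq_along(lo) - 1))
}

# y[t] = sum_k taps[k] x[t - k*up] (periodic)
oracleCircConv <- function(x, taps, up) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(taps))
    out <- out + taps[k] * x[((seq_len(n) - 1 - (k - 1) * up) %% n) + 1]
  out
}

oracleConv2 <- function(img, tapsRow, tapsCol, up) {
  tmp <- apply(img, 2, oracleCircConv, taps = tapsRow, up = up)
  t(apply(tmp, 1, oracleCircConv, taps = tapsCol, up = up))
}

# full multilevel analysis, 0.5 scaling per 2-D split; returns an array
# with the package's subband ordering (LH, HL, HH per level, LL last)
oracleSWT <- function(img, wavelet, levels) {
  f <- oracleFilters(wavelet)
  out <- array(0, c(nrow(img), ncol(img), 3 * levels + 1))
  ll <- img
  s <- 1
  for (j in seq_len(levels)) {
    up <- 2^(j - 1)
    out[, , s]     <- 0.5 * oracleConv2(ll, f$lo, f$hi, up)
    out[, , s + 1] <- 0.5 * oracleConv2(ll, f$hi, f$lo, up)
    out[, , s + 2] <- 0.5 * oracleConv2(ll, f$hi, f$hi, up)
    ll             <- 0.5 * oracleConv2(ll, f$lo, f$lo, up)
    s <- s + 3
  }
  out[, , 3 * levels + 1] <- ll
  out
}

# -- brute-force block matching -----------------------------------------

# candidate window identical to the documented contract: T x T centered on
# the reference patch, clipped to the image, candidates fully inside
oracleWindow <- function(r0, n, L, Tw) {
  w0 <- max(1, r0 + L %/% 2 - Tw %/% 2)
  w1 <- min(n, w0 + Tw - 1)
  w0 <- max(1, w1 - Tw + 1)
  c(max(1, w0), min(n - L + 1, w1 - L + 1))
}

oracleBlockMatch <- function(img, ref, L, Tw, cgs) {
  rr <- oracleWindow(ref[1], nrow(img), L, Tw)
  cr <- oracleWindow(ref[2], ncol(img), L, Tw)
  refP <- img[ref[1]:(ref[1] + L - 1), ref[2]:(ref[2] + L - 1)]
  rows <- integer(0); cols <- integer(0); d <- numeric(0)
  for (i in rr[1]:rr[2]) for (j in cr[1]:cr[2]) {   # raster order
    if (i == ref[1] && j == ref[2]) next
    p <- img[i:(i + L - 1), j:(j + L - 1)]
    rows <- c(rows, i); cols <- c(cols, j)
    d <- c(d, sum((p - refP)^2))
  }
  o <- order(d, seq_along(d))  # stable: ties keep raster order
  take <- head(o, cgs - 1)
  if (length(take) < cgs - 1)
    take <- c(take, rep(take[length(take)], cgs - 1 - length(take)))
  cbind(c(ref[1], rows[take]), c(ref[2], cols[take]))
}

# -- dense operators ----------------------------------------------------

# dense matrix of the nonlocal normal operator sum_p (Psi_p^3D)^T Psi_p^3D
oracleGroupNormalDense <- function(groups) {
  n <- prod(groups@shape)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- matrix(0, groups@shape[1], groups@shape[2])
    e[i] <- 1
    A[, i] <- as.vector(groupAdjoint(groupForward(e, groups), groups))
  }
  A
}

# brute-force per-pixel coverage accumulation, patch by patch
oracleCoverage <- function(groups) {
  cov <- matrix(0, groups@shape[1], groups@shape[2])
  L <- groups@patchSize
  for (p in seq_len(nrow(groups@refCoords))) {
    for (m in seq_len(groups@groupSize)) {
      r <- groups@memberRows[m, p]; cc <- groups@memberCols[m, p]
      cov[r:(r + L - 1), cc:(cc + L - 1)] <-
        cov[r:(r + L - 1), cc:(cc + L - 1)] + 1
    }
  }
  cov
}

# -- scalar proximal oracle ---------------------------------------------

# grid minimization of w*|r| + lam/2*(r - v)^2
oracleProx <- function(v, w, lam, lim = 2.5, np = 40001) {
  grid <- seq(-lim, lim, length.out = np)
  grid[which.min(w * abs(grid) + lam / 2 * (grid - v)^2)]
}

relErr <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
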