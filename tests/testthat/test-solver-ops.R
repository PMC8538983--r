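test_that("shrink implements the soft-threshold closed form", {
  expect_equal(shrink(0.5, 1), 0)
  expect_equal(shrink(2, 0.5), 1.5)
  expect_equal(shrink(-3, 1), -2)
  v <- seq(-4, 4, by = 0.25)
  expect_equal(shrink(v, 0), v)
  expect_equal(shrink(v, 1.25), sign(v) * pmax(abs(v) - 1.25, 0))
  # array thresholds broadcast elementwise
  t2 <- abs(v) / 2
  expect_equal(shrink(v, t2), sign(v) * pmax(abs(v) - t2, 0))
  expect_error(shrink(v, -1), "nonnegative")
})

test_that("xUpdate reduces to the elementwise closed form when priors vanish", {
  cfg <- suppressWarnings(solverConfig(mu = 1, lambda = 1, gamma = 0,
                                       baseA = 10, weighted = FALSE,
                                       wavelet = "db2", levels = 2L))
  mask <- randomMask(c(16, 16), 0.25, seed = 4)
  set.seed(41)
  y <- runif(nrow(maskIndices(mask)))
  st <- initBregmanState(y, mask, cfg)
  st$rE <- array(0, dim(st$rE)); st$bR <- array(0, dim(st$bR))
  x <- xUpdate(st, y, mask, cfg)
  ind <- maskIndicator(mask)
  # sampled pixels: mu*y/(mu+lambda) = y/2; unsampled: 0
  expect_equal(measure(x, mask), y / 2)
  expect_true(all(x[ind == 0] == 0))
})

test_that("xUpdate is stationary at a consistent full-sampling state", {
  cfg <- suppressWarnings(solverConfig(gamma = 0))
  mask <- randomMask(c(16, 16), 1.0, seed = 1)
  img <- phantomImage(seedPhantom(c(32, 32), 5))[1:16, 1:16]
  y <- measure(img, mask)
  st <- initBregmanState(y, mask, cfg)   # warm start is exactly img here
  expect_equal(st$x, img)
  expect_lt(max(abs(xUpdate(st, y, mask, cfg) - img)), 1e-12)
})

test_that("xUpdate matches a dense brute-force solve of the normal equations", {
  set.seed(42)
  cfg <- solverConfig(mu = 3, lambda = 2, gamma = 1.5, levels = 2L,
                      patchSize = 8L, stride = 4L, searchWin = 40L,
                      groupSize = 10L)
  mask <- randomMask(c(12, 12), 0.4, seed = 6)
  y <- runif(nrow(maskIndices(mask)))
  st <- initBregmanState(y, mask, cfg)
  # perturb the split/Bregman variables so the RHS is generic
  st$rE <- array(runif(length(st$rE), -0.5, 0.5), dim(st$rE))
  st$bR <- array(runif(length(st$bR), -0.1, 0.1), dim(st$bR))
  st$theta <- st$theta + array(rnorm(length(st$theta), sd = 0.1),
                               dim(st$theta))
  st$bTheta <- array(rnorm(length(st$bTheta), sd = 0.05), dim(st$bTheta))
  got <- xUpdate(st, y, mask, cfg)

  # dense normal matrix: mu R^T R + lambda I + gamma sum_p (...)^T (...)
  N <- 144
  A <- cfg@mu * diag(as.vector(maskIndicator(mask))) + cfg@lambda * diag(N) +
    cfg@gamma * oracleGroupNormalDense(st$groups)
  wc <- new("WaveletCoeffs",
            coeffs = array(thzrecon:::.expInvArr(st$rE - st$bR, cfg@baseA,
                                                 st$scale),
                           dim(st$rE)),
            wavelet = cfg@wavelet, levels = cfg@levels)
  z <- cfg@mu * maskAdjoint(y, mask) + cfg@lambda * swtAdjoint(wc) +
    cfg@gamma * groupAdjoint(st$theta - st$bTheta, st$groups)
  want <- matrix(solve(A, as.vector(z)), 12, 12)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("thetaUpdate soft-thresholds the grouped transform at 1/gamma", {
  set.seed(43)
  cfg <- solverConfig(gamma = 4, patchSize = 4L, stride = 4L,
                      searchWin = 8L, groupSize = 4L, levels = 2L)
  mask <- randomMask(c(16, 16), 0.5, seed = 2)
  y <- runif(nrow(maskIndices(mask)))
  st <- initBregmanState(y, mask, cfg)
  st$bTheta <- array(rnorm(length(st$bTheta), sd = 0.2), dim(st$bTheta))
  up <- thetaUpdate(st, cfg)
  # elementwise oracle at threshold 1/gamma
  arg <- coeffArray(groupForward(st$x, st$groups)) + st$bTheta
  want <- array(vapply(as.vector(arg),
                       function(a) sign(a) * max(abs(a) - 1 / 4, 0),
                       numeric(1)), dim(arg))
  expect_equal(up$theta, want)
  # gamma -> Inf limit: threshold -> 0, output equals input
  cfgInf <- cfg; cfgInf@gamma <- 1e12
  expect_lt(max(abs(thetaUpdate(st, cfgInf)$theta - arg)), 1e-10)
  cfg0 <- cfg; cfg0@gamma <- 0
  expect_error(thetaUpdate(st, cfg0), "gamma")
})

test_that("reUpdate solves the weighted proximal problem exactly", {
  set.seed(44)
  cfg <- suppressWarnings(solverConfig(lambda = 3, gamma = 0, baseA = 10,
                                       weighted = TRUE, levels = 2L))
  mask <- randomMask(c(16, 16), 0.5, seed = 8)
  y <- runif(nrow(maskIndices(mask)))
  st <- initBregmanState(y, mask, cfg)
  st$bR <- array(rnorm(length(st$bR), sd = 0.3), dim(st$bR))
  st$weights <- array(runif(length(st$rE), 0.5, 3), dim(st$rE))
  up <- reUpdate(st, cfg)
  v <- up$ePsi + st$bR
  # per-entry exhaustive 1-D minimization of w|r| + lambda/2 (r - v)^2
  pick <- sample(length(v), 25)
  for (k in pick) {
    expect_lt(abs(up$rE[k] - oracleProx(v[k], st$weights[k], cfg@lambda)),
              2e-4)
  }
  # weights refreshed from the new rE by the magnitude-inverse law
  expect_equal(up$weights, computeWeights(up$rE, cfg@delta))

  # uniform weights reduce to a plain soft threshold at w/lambda
  st$weights <- array(2, dim(st$rE))
  up2 <- reUpdate(st, cfg)
  expect_equal(up2$rE, shrink(up2$ePsi + st$bR, 2 / 3))

  # zero-weight limit: no penalty, rE = v unchanged
  st$weights <- array(0, dim(st$rE))
  cfgU <- cfg; cfgU@weighted <- FALSE
  up3 <- reUpdate(st, cfgU)
  expect_equal(up3$rE, up3$ePsi + st$bR)
})

test_that("Bregman variables accumulate the split residuals telescopically", {
  set.seed(45)
  dims <- c(6, 6, 4)
  st <- list(rE = array(rnorm(prod(dims)), dims),
             ePsi = array(rnorm(prod(dims)), dims),
             bR = array(0, dims), theta = NULL)
  # consistent split: b unchanged
  stc <- st; stc$rE <- stc$ePsi
  expect_equal(bregmanUpdate(stc)$bR, array(0, dims))
  # first step from zero: b equals the constraint residual
  expect_equal(bregmanUpdate(st)$bR, st$ePsi - st$rE)
  # five steps telescope to the running sum of residuals
  acc <- array(0, dims)
  for (i in 1:5) {
    st$ePsi <- array(rnorm(prod(dims)), dims)
    st$rE <- array(rnorm(prod(dims)), dims)
    acc <- acc + (st$ePsi - st$rE)
    st <- bregmanUpdate(st)
  }
  expect_equal(st$bR, acc)
})
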