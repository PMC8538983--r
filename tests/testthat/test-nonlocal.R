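test_that("the reference grid steps by the stride and covers the borders", {
  expect_equal(extractPatchGrid(c(8, 8), 8, 4), cbind(row = 1L, col = 1L))
  g <- extractPatchGrid(c(12, 12), 8, 4)
  expect_equal(nrow(g), 4L)                       # starts {1, 5} per axis
  expect_equal(sort(unique(g[, "row"])), c(1L, 5L))
  # clamped final start: 13x13 -> starts {1, 5, 6}
  g2 <- extractPatchGrid(c(13, 13), 8, 4)
  expect_equal(sort(unique(g2[, "row"])), c(1L, 5L, 6L))
  expect_error(extractPatchGrid(c(6, 6), 8, 4), "patch")
})

test_that("block matching ranks by distance with raster-order tie-breaks", {
  # constant image: all distances tie; members are the reference followed
  # by the first c-1 window candidates in raster order
  img <- matrix(0.5, 20, 20)
  bm <- blockMatch(img, c(5, 5), L = 4, Tw = 8, c = 5)
  expect_equal(unname(bm[1, ]), c(5, 5))
  # clipped window rows/cols 3..10 admit top-left positions 3..7
  cand <- expand.grid(col = 3:7, row = 3:7)[, c("row", "col")]
  cand <- cand[!(cand$row == 5 & cand$col == 5), ]
  cand <- cand[order(cand$row, cand$col), ]
  expect_equal(unname(bm[-1, ]), unname(as.matrix(cand[1:4, ])))

  # an exact duplicate of the reference patch ranks second
  set.seed(31)
  img <- matrix(runif(30 * 30), 30, 30)
  img[10:13, 20:23] <- img[4:7, 6:9]
  bm <- blockMatch(img, c(4, 6), L = 4, Tw = 40, c = 6)
  expect_equal(unname(bm[2, ]), c(10, 20))
})

test_that("fast grouping equals exhaustive brute-force matching", {
  set.seed(32)
  img <- matrix(rnorm(40 * 40), 40, 40)
  groups <- buildPatchGroups(img, L = 8, stride = 4, Tw = 40, c = 10)
  for (p in c(1, 7, nrow(groups@refCoords))) {
    want <- oracleBlockMatch(img, groups@refCoords[p, ], 8, 40, 10)
    expect_equal(unname(cbind(groups@memberRows[, p], groups@memberCols[, p])),
                 unname(want))
    # the standalone matcher agrees too
    expect_equal(unname(blockMatch(img, groups@refCoords[p, ], 8, 40, 10)),
                 unname(want))
  }
  expect_equal(groups@padCount, 0L)
})

test_that("the grouped 3-D transform is orthonormal per group", {
  set.seed(33)
  img <- matrix(rnorm(24 * 24), 24, 24)
  groups <- buildPatchGroups(img, L = 8, stride = 4, Tw = 16, c = 10)
  th <- groupForward(img, groups)
  v <- coeffArray(th)
  L <- groups@patchSize
  for (p in c(1, 5)) {
    z <- vapply(seq_len(groups@groupSize), function(m) {
      r <- groups@memberRows[m, p]; cc <- groups@memberCols[m, p]
      as.vector(img[r:(r + L - 1), cc:(cc + L - 1)])
    }, numeric(L * L))
    expect_lt(relErr(sum(v[, , p]^2), sum(z^2)), 1e-12)  # energy preserved
  }
  expect_equal(coeffArray(groupForward(matrix(0, 24, 24), groups)),
               array(0, dim(v)))
})

test_that("identical stacked patches concentrate energy in the first similarity slice", {
  # image tiled so every patch in the window equals the reference patch
  tile <- matrix(rnorm(4 * 4), 4, 4)
  img <- tile[rep(1:4, 4), rep(1:4, 4)]          # 16 x 16 periodic tiling
  # the 16 x 16 window always holds >= 4 exact copies of the reference
  groups <- buildPatchGroups(img, L = 4, stride = 4, Tw = 16, c = 4)
  v <- coeffArray(groupForward(img, groups))
  # c = 4 is a power of two -> Haar along the similarity axis; all member
  # patches are identical, so slices 2..c vanish
  expect_lt(max(abs(v[, -1, ])), 1e-12)
  expect_gt(sum(v[, 1, ]^2), 0)
})

test_that("groupAdjoint is the exact adjoint and the normal operator is the coverage diagonal", {
  set.seed(34)
  img <- matrix(rnorm(32 * 32), 32, 32)
  groups <- buildPatchGroups(img, L = 8, stride = 4, Tw = 40, c = 10)
  th <- coeffArray(groupForward(img, groups))
  r <- array(rnorm(length(th)), dim(th))
  lhs <- sum(th * r)
  rhs <- sum(img * groupAdjoint(r, groups))
  expect_lt(relErr(lhs, rhs), 1e-10)

  cov <- coverageDiagonal(groups)
  expect_lt(max(abs(groupAdjoint(th, groups) - cov * img)), 1e-10)
  expect_equal(groupAdjoint(array(0, dim(th)), groups), matrix(0, 32, 32))
})

test_that("coverage counts match brute-force patch accumulation exactly", {
  set.seed(35)
  img <- matrix(rnorm(24 * 24), 24, 24)
  groups <- buildPatchGroups(img, L = 8, stride = 4, Tw = 16, c = 6)
  expect_identical(coverageDiagonal(groups), oracleCoverage(groups))
  # trivial cases: a single patch covers its own footprint once
  g1 <- buildPatchGroups(matrix(0, 32, 32), L = 2, stride = 31, Tw = 4, c = 2)
  expect_equal(sum(coverageDiagonal(g1)),
               2 * 2 * 2 * nrow(g1@refCoords))
})

test_that("tiny windows pad groups by repeating the last candidate", {
  img <- matrix(seq_len(100) / 100, 10, 10)
  # window barely larger than the patch: fewer candidates than c
  groups <- buildPatchGroups(img, L = 8, stride = 8, Tw = 10, c = 10)
  expect_gt(groups@padCount, 0L)
  expect_equal(dim(groups@memberRows), c(10L, nrow(groups@refCoords)))
  # grouping is still valid and round-trips through the transform
  th <- groupForward(img, groups)
  expect_equal(dim(coeffArray(th))[2], 10L)
})
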