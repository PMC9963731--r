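test_that("PCA band model matches a dense eigendecomposition oracle", {
  one <- HSCube(array(runif(16), c(4, 4, 1)))
  m1 <- fitPCABand(one)
  expect_equal(m1@loadings, 1)
  expect_equal(m1@varianceRatio, 1)

  set.seed(3)
  b0 <- matrix(runif(64), 8, 8)
  rank1 <- HSCube(array(c(b0, 2 * b0), c(8, 8, 2)))
  expect_equal(fitPCABand(rank1)@varianceRatio, 1, tolerance = 1e-12)

  cube <- randomCube(32, 32, 6, seed = 19)
  model <- suppressWarnings(fitPCABand(cube))
  X <- matrix(cubeData(cube), 32 * 32, 6)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(model@varianceRatio, ev$values[1] / sum(ev$values),
               tolerance = 1e-8)
  expect_equal(abs(model@loadings), abs(ev$vectors[, 1]), tolerance = 1e-8)
  expect_equal(sum(model@loadings^2), 1, tolerance = 1e-12)
  expect_gt(model@loadings[which.max(abs(model@loadings))], 0)

  expect_error(fitPCABand(HSCube(array(2, c(4, 4, 3)))), "flat")
  # iid bands: leading component cannot reach 65% -> warning, not error
  noisy <- randomCube(24, 24, 8, seed = 23)
  expect_warning(fitPCABand(noisy), "65")
})

test_that("band projection reproduces loadings algebra", {
  cube <- randomCube(16, 16, 4, seed = 29)
  model <- suppressWarnings(fitPCABand(cube))
  proj <- projectBand(cube, model)
  X <- matrix(cubeData(cube), 256, 4)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(var(as.vector(proj)), ev$values[1], tolerance = 1e-8)

  flat <- HSCube(array(5, c(4, 4, 4)))
  idModel <- new("PCABandModel", loadings = c(1, 0, 0, 0),
                 meanSpectrum = rep(0, 4), varianceRatio = 1)
  expect_true(all(projectBand(flat, idModel) == 5))
  expect_equal(projectBand(cube, idModel), selectBand(cube, 0))
  expect_error(projectBand(randomCube(4, 4, 3), model), "bands")
})

test_that("SAD is the absolute-difference sum", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(sadCost(a, a), 0)
  expect_identical(sadCost(matrix(1), matrix(4)), 3)
  set.seed(7)
  b <- matrix(runif(64), 8, 8)
  s <- 0
  for (i in 1:8) for (j in 1:8) s <- s + abs(a[i, j] - b[i, j])
  expect_equal(sadCost(a, b), s)
  expect_error(sadCost(a, matrix(0, 4, 4)), "shape")
})

test_that("full-search integer matching equals the exhaustive oracle", {
  img <- texturedImage(40, 40, seed = 2)
  m0 <- fsbmInteger(img[9:24, 9:24], c(8, 8), img, 4)
  expect_identical(c(m0$dyQ, m0$dxQ), c(0L, 0L))
  expect_identical(m0$sad, 0)

  # rolled target recovered exactly on an interior block
  rolled <- img[c(3:40, 1:2), c(40, 1:39)]   # content moved by (-2, +1)...
  # rolling rows by 2 upward means the block at (8,8) appears at (6,8):
  m <- fsbmInteger(img[13:28, 13:28], c(12, 12), rolled, 4)
  expect_identical(c(m$dyQ, m$dxQ) %/% 4L, c(-2L, 1L))

  set.seed(101)
  for (rep in 1:25) {
    h <- sample(24:48, 1); w <- sample(24:48, 1)
    target <- matrix(runif(h * w), h, w)
    bs <- sample(c(8, 12, 16), 1)
    oy <- sample(0:(h - bs), 1); ox <- sample(0:(w - bs), 1)
    rg <- sample(1:4, 1)
    block <- target[(oy + 1):(oy + bs), (ox + 1):(ox + bs)] +
      matrix(rnorm(bs * bs, sd = 0.05), bs, bs)
    got <- fsbmInteger(block, c(oy, ox), target, rg)
    want <- naiveFsbm(block, c(oy, ox), target, rg)
    expect_identical(c(got$dyQ, got$dxQ),
                     as.integer(4 * want[c("dy", "dx")]),
                     label = paste("instance", rep))
    expect_equal(got$sad, unname(want["sad"]), tolerance = 1e-9)
  }

  flat <- fsbmInteger(matrix(1, 8, 8), c(8, 8), matrix(1, 24, 24), 4)
  expect_identical(c(flat$dyQ, flat$dxQ), c(0L, 0L))
  expect_true(flat$lowConfidence)
  expect_error(fsbmInteger(matrix(1, 30, 30), c(0, 0), matrix(1, 8, 8), 2),
               "no valid candidate")
})

test_that("sub-pixel refinement finds injected fractional shifts and never increases SAD", {
  img <- texturedImage(40, 40, seed = 9)
  # integer-shifted target: refinement keeps the integer winner
  shifted <- img[c(2:40, 1), ]
  m <- fsbmInteger(img[13:28, 13:28], c(12, 12), shifted, 4)
  r <- refineSubpixel(m, img[13:28, 13:28], shifted)
  expect_identical(c(r$dyQ, r$dxQ), c(m$dyQ, m$dxQ))
  expect_lte(r$sad, m$sad)

  # column ramp resampled by half a pixel: dxQ = +-2 recovered exactly
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32)
  half <- (ramp + cbind(ramp[, -1], ramp[, 32])) / 2   # ramp shifted by +0.5
  mi <- fsbmInteger(ramp[9:24, 9:24], c(8, 8), half, 4)
  ri <- refineSubpixel(mi, ramp[9:24, 9:24], half)
  expect_identical(abs(ri$dxQ), 2L)
  expect_identical(ri$dyQ, 0L)

  # property: SAD non-increasing across refinement on random textures
  set.seed(55)
  for (rep in 1:10) {
    target <- texturedImage(36, 36, seed = 100 + rep)
    block <- target[11:26, 11:26] + matrix(rnorm(256, sd = 0.02), 16, 16)
    m <- fsbmInteger(block, c(10, 10), target, 3)
    r <- refineSubpixel(m, block, target)
    expect_lte(r$sad, m$sad)
    expect_true(all(abs(c(r$dyQ - m$dyQ, r$dxQ - m$dxQ)) <= 3))
  }

  flatM <- fsbmInteger(matrix(1, 8, 8), c(8, 8), matrix(1, 24, 24), 2)
  expect_identical(refineSubpixel(flatM, matrix(1, 8, 8), matrix(1, 24, 24)),
                   flatM)
})

test_that("global motion is the median of block vectors and matches simulator truth", {
  band <- texturedImage(64, 64, seed = 3)
  same <- estimateGlobalMotion(band, band, mbSize = 16, searchRange = 4)
  expect_identical(c(same$global@dyQ, same$global@dxQ), c(0L, 0L))
  expect_equal(same$global@agreement, 1)

  # simulator ground truth, label (-2, 3)... use integer HR shifts
  ph <- makePhantom(phantomSpec(seed = 41))
  gen <- generateSequence(ph, 8, 8, 112, rbind(c(0L, 0L), c(1L, -1L)), 2)
  expect_identical(gen$seq@labels[2, ], c(-2L, 2L))
  est <- estimateSequenceMotion(gen$seq)
  expect_identical(motionMatrix(est$motions)[2, ], gen$seq@labels[2, ])

  # a corrupted macroblock cannot move the median
  frame <- band
  frame[25:40, 25:40] <- matrix(runif(256), 16, 16)   # noise burst
  est2 <- estimateGlobalMotion(frame, band, mbSize = 16, searchRange = 4)
  expect_identical(c(est2$global@dyQ, est2$global@dxQ), c(0L, 0L))
  expect_gte(est2$global@nBlocks, 9L)

  expect_error(estimateGlobalMotion(matrix(1, 32, 32), matrix(1, 32, 32)),
               "untextured")
})
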