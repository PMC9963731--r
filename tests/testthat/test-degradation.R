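test_that("average pooling matches the block-mean oracle and composes", {
  expect_equal(averagePool(matrix(c(1, 3, 2, 4), 2, 2), 2),
               matrix(2.5, 1, 1))
  expect_equal(averagePool(matrix(7, 8, 8), 4), matrix(7, 2, 2))
  set.seed(4)
  img <- matrix(runif(16 * 16), 16, 16)
  pooled <- averagePool(img, 4)
  for (i in 1:4) for (j in 1:4)
    expect_equal(pooled[i, j],
                 mean(img[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]))
  # integer-valued data: pooling twice by 2 equals pooling once by 4 exactly
  set.seed(5)
  ints <- matrix(sample.int(10000, 16 * 16, replace = TRUE), 16, 16)
  expect_identical(averagePool(averagePool(ints, 2), 2),
                   averagePool(ints, 4))
  expect_error(averagePool(matrix(0, 5, 4), 2), "divisible")
})

test_that("default shift pattern covers all sub-pixel phases without duplicates", {
  expect_identical(defaultShiftPattern(2, 1),
                   matrix(0L, 1, 2, dimnames = list(NULL, c("dy_hr", "dx_hr"))))
  p4 <- defaultShiftPattern(2, 4)
  expect_setequal(apply(p4, 1, paste, collapse = ","),
                  c("0,0", "0,1", "1,0", "1,1"))
  p16 <- defaultShiftPattern(4, 16)
  phases <- apply(p16 %% 4L, 1, paste, collapse = ",")
  expect_identical(sort(phases),
                   sort(as.vector(outer(0:3, 0:3, paste, sep = ","))))
  # deterministic, starts at the origin, extends to any n
  expect_identical(defaultShiftPattern(4, 30), defaultShiftPattern(4, 30))
  expect_identical(defaultShiftPattern(2, 9)[1, ],
                   c(dy_hr = 0L, dx_hr = 0L))
  expect_identical(nrow(defaultShiftPattern(2, 40)), 40L)
  # all offsets needed for full phase coverage stay within 2 pixels
  expect_true(all(abs(p16) <= 2))
})

test_that("generateSequence pools shifted crops and labels content motion", {
  cube <- randomCube(24, 24, 3, seed = 6)
  gen <- generateSequence(cube, 2, 2, 16, matrix(c(0L, 0L), 1), 2)
  expect_length(gen$seq@frames, 1)
  expect_identical(gen$seq@labels, matrix(c(0L, 0L), 1))
  pooled <- vapply(1:3, function(b) averagePool(selectBand(gen$vhri, b - 1), 2),
                   matrix(0, 8, 8))
  expect_equal(cubeData(gen$seq@frames[[1]]), array(pooled, c(8, 8, 3)))
  expect_identical(dim(gen$vhri), c(16L, 16L, 3L))

  # linear-ramp closed form: HR ramp r(row, col) = col, ef = 2, shift (1, 1).
  # Pooled reference value at LR col j is the mean of HR cols 2j, 2j+1; the
  # shifted window advances every block by one HR column, so the frame equals
  # the reference plus the HR slope (1) everywhere = half an LR pixel of the
  # LR ramp (slope 2/LR px).
  ramp <- HSCube(array(rep(0:23, each = 24), c(24, 24, 1)) + 1)
  genR <- generateSequence(ramp, 2, 2, 16, rbind(c(0L, 0L), c(1L, 1L)), 2)
  expect_identical(genR$seq@labels[2, ], c(-2L, -2L))
  expect_equal(cubeData(genR$seq@frames[[2]])[, , 1],
               cubeData(genR$seq@frames[[1]])[, , 1] + 1)

  # label formula holds for every ef and shift
  shifts <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 2L), c(-1L, 1L), c(2L, -2L))
  for (ef in c(2L, 4L)) {
    g <- generateSequence(cube, 4, 4, 16, shifts, ef)
    expect_identical(g$seq@labels, -shifts * (4L %/% ef) * 1L)
    expect_identical(g$seq@ef, ef)
  }

  # ef = 4 over the 16 canonical shifts covers every quarter phase once
  big <- randomCube(28, 28, 2, seed = 13)
  shifts16 <- as.matrix(expand.grid(dy = 0:3, dx = 0:3))
  shifts16 <- shifts16[order(shifts16[, 1], shifts16[, 2]), ]
  g16 <- generateSequence(big, 2, 2, 16, shifts16, 4)
  expect_identical(nrow(unique(g16$seq@labels %% 4L)), 16L)

  expect_error(generateSequence(cube, 20, 20, 16, rbind(c(0L, 0L)), 2),
               "outside")
  expect_error(generateSequence(cube, 0, 0, 16,
                                rbind(c(0L, 0L), c(20L, 0L)), 2),
               "out of bounds")
})

test_that("motion is invisible on constant scenes", {
  flat <- HSCube(array(3, c(24, 24, 2)))
  g <- generateSequence(flat, 2, 2, 16,
                        rbind(c(0L, 0L), c(1L, 1L), c(2L, 0L)), 2)
  for (f in g$seq@frames) expect_true(all(cubeData(f) == 3))
})

test_that("phantom generation is seed-deterministic with the stated structure", {
  spec <- phantomSpec(height = 64, width = 64, nBands = 6, seed = 21)
  a <- makePhantom(spec); b <- makePhantom(spec)
  expect_identical(cubeData(a), cubeData(b))
  other <- makePhantom(phantomSpec(height = 64, width = 64, nBands = 6,
                                   seed = 22))
  expect_false(identical(cubeData(a), cubeData(other)))

  # texture-only cube when blobs and noise are off
  plain <- makePhantom(phantomSpec(height = 48, width = 48, nBands = 3,
                                   nBlobs = 0, noiseSigma = 0, seed = 1))
  expect_identical(cubeData(plain), cubeData(makePhantom(
    phantomSpec(height = 48, width = 48, nBands = 3, nBlobs = 0,
                noiseSigma = 0, seed = 1))))

  # full band correlation: every band is a scalar multiple of band 0
  corr1 <- makePhantom(phantomSpec(height = 48, width = 48, nBands = 5,
                                   noiseSigma = 0, bandCorrelation = 1,
                                   seed = 3))
  b0 <- selectBand(corr1, 0)
  expect_true(min(cubeData(corr1)) > 0)
  for (b in 1:4) {
    ratio <- selectBand(corr1, b) / b0
    expect_lt(diff(range(ratio)), 1e-9)
  }

  # every 16 x 16 tile carries gradient energy, so block matching is well-posed
  ph <- makePhantom(phantomSpec(seed = 2))
  band <- selectBand(ph, 0)
  for (i in seq(1, 113, by = 16)) {
    for (j in seq(1, 113, by = 16)) {
      tile <- band[i:(i + 15), j:(j + 15)]
      expect_gt(sd(tile), 0)
    }
  }
})

test_that("sequences round-trip through the on-disk manifest format", {
  cube <- randomCube(24, 24, 3, seed = 17)
  gen <- generateSequence(cube, 2, 2, 16,
                          rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L)), 2)
  dir <- withr::local_tempdir()
  writeSequence(gen$seq, dir)
  expect_true(file.exists(file.path(dir, "sequence.json")))
  back <- readSequence(dir)
  expect_identical(back@labels, gen$seq@labels)
  expect_identical(back@ef, gen$seq@ef)
  expect_identical(back@referenceIndex, gen$seq@referenceIndex)
  for (i in seq_along(back@frames))
    expect_identical(cubeData(back@frames[[i]]),
                     cubeData(gen$seq@frames[[i]]))
})
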