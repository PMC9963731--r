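test_that("HSCube validity enforces shape, wavelength axis and finiteness", {
  expect_error(HSCube(array(0, c(2, 2, 3)), wavelengths = c(500, 600)),
               "band-axis")
  expect_error(HSCube(array(0, c(2, 2, 2)), wavelengths = c(600, 500)),
               "increasing")
  bad <- array(0, c(2, 2, 2)); bad[1] <- NaN
  expect_error(HSCube(bad, wavelengths = c(1, 2)), "NaN")
  cube <- HSCube(array(1:8, c(2, 2, 2)))
  expect_true(isTRUE(metaData(cube)$syntheticWavelengths))
  expect_identical(wavelengths(cube), c(1, 2))
})

test_that("cropSpatial uses 0-based half-open windows and composes", {
  cube <- randomCube(10, 10, 3)
  expect_identical(cubeData(cropSpatial(cube, 0, 0, 10, 10)),
                   cubeData(cube))
  cr <- cropSpatial(cube, 2, 3, 4, 4)
  expect_identical(cubeData(cr), cubeData(cube)[3:6, 4:7, , drop = FALSE])
  # composition: crop of a crop is a single crop with summed offsets
  twice <- cropSpatial(cropSpatial(cube, 1, 2, 7, 6), 2, 1, 3, 3)
  once <- cropSpatial(cube, 3, 3, 3, 3)
  expect_identical(cubeData(twice), cubeData(once))
  expect_error(cropSpatial(cube, 8, 0, 4, 4), "outside")
  # overlapping crops agree on the overlap and differ elsewhere
  a <- cropSpatial(cube, 0, 0, 6, 6)
  b <- cropSpatial(cube, 2, 2, 6, 6)
  expect_identical(cubeData(a)[3:6, 3:6, ], cubeData(b)[1:4, 1:4, ])
})

test_that("selectBand slices with copy semantics and matches direct indexing", {
  perBand <- array(rep(0:2, each = 4), c(2, 2, 3))
  cube <- HSCube(perBand)
  expect_identical(selectBand(cube, 2), matrix(2, 2, 2))
  one <- HSCube(array(5, c(3, 3, 1)))
  expect_identical(selectBand(one, 0), matrix(5, 3, 3))
  expect_error(selectBand(one, 1), "out of range")
  cube2 <- randomCube(5, 4, 6, seed = 9)
  for (b in 0:5) {
    oracle <- matrix(NA_real_, 5, 4)
    for (i in 1:5) for (j in 1:4) oracle[i, j] <- cubeData(cube2)[i, j, b + 1]
    expect_identical(selectBand(cube2, b), oracle)
  }
  img <- selectBand(cube2, 0)
  img[1, 1] <- -999
  expect_false(cubeData(cube2)[1, 1, 1] == -999)
})

test_that("ENVI round-trips are bit-exact and interleaves agree", {
  cube <- randomCube(8, 8, 5, seed = 3)   # float32-representable values
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "cube.img")
  writeCube(cube, p, format = "envi", dtype = "float32")
  back <- readCube(p, format = "envi")
  expect_identical(cubeData(back), cubeData(cube))
  expect_identical(wavelengths(back), wavelengths(cube))
  # all interleave dialects of one array read back identically
  for (il in c("bsq", "bil", "bip")) {
    pi <- file.path(tmp, paste0("cube_", il, ".img"))
    writeCube(cube, pi, format = "envi", interleave = il)
    expect_identical(cubeData(readCube(pi, format = "envi")),
                     cubeData(cube), label = il)
  }
  # known 2x2x2 ramp through BIL equals its BSQ encoding
  ramp <- HSCube(array(as.numeric(1:8), c(2, 2, 2)), wavelengths = c(1, 2))
  writeCube(ramp, file.path(tmp, "ramp_bsq.img"), "envi", interleave = "bsq")
  writeCube(ramp, file.path(tmp, "ramp_bil.img"), "envi", interleave = "bil")
  expect_identical(
    cubeData(readCube(file.path(tmp, "ramp_bil.img"), "envi")),
    cubeData(readCube(file.path(tmp, "ramp_bsq.img"), "envi")))
  # uint16 raw cube
  raw <- HSCube(array(sample.int(65535, 60) - 1L, c(5, 4, 3)))
  writeCube(raw, file.path(tmp, "raw.img"), "envi", dtype = "uint16")
  expect_identical(cubeData(readCube(file.path(tmp, "raw.img"), "envi")),
                   cubeData(raw))
  # scalar meta survives as header strings
  cube@meta <- list(magnification = "10x", calibrated = "yes")
  writeCube(cube, file.path(tmp, "meta.img"), "envi")
  mm <- metaData(readCube(file.path(tmp, "meta.img"), "envi"))
  expect_identical(mm$magnification, "10x")
  expect_identical(mm$calibrated, "yes")
})

test_that("HDF5 round-trips are bit-exact with meta preserved field by field", {
  tmp <- withr::local_tempdir()
  set.seed(11)
  cube <- HSCube(array(runif(8 * 8 * 5), c(8, 8, 5)),
                 wavelengths = seq(450, 850, length.out = 5),
                 meta = list(magnification = "20x", nLines = 100,
                             calibrated = TRUE))
  p <- file.path(tmp, "cube.h5")
  writeCube(cube, p, format = "hdf5")
  back <- readCube(p, format = "hdf5")
  expect_identical(cubeData(back), cubeData(cube))
  expect_identical(wavelengths(back), wavelengths(cube))
  expect_identical(metaData(back)$magnification, "20x")
  expect_identical(metaData(back)$nLines, 100L)
  expect_identical(metaData(back)$calibrated, TRUE)
  small <- HSCube(array(as.numeric(1:48), c(4, 4, 3)),
                  wavelengths = c(500, 600, 700))
  p2 <- file.path(tmp, "small.h5")
  writeCube(small, p2, format = "hdf5")
  expect_equal(nBands(readCube(p2, format = "hdf5")), 3)
})

test_that("missing wavelength metadata yields a flagged synthetic axis", {
  tmp <- withr::local_tempdir()
  cube <- randomCube(4, 4, 3)
  p <- file.path(tmp, "nowl.img")
  writeCube(cube, p, format = "envi")
  hdr <- readLines(file.path(tmp, "nowl.hdr"))
  writeLines(hdr[!grepl("^wavelength", hdr)], file.path(tmp, "nowl.hdr"))
  back <- readCube(p, format = "envi")
  expect_identical(wavelengths(back), c(1, 2, 3))
  expect_true(isTRUE(metaData(back)$syntheticWavelengths))
})

test_that("MAT v5 import agrees with scipy-written files", {
  tmp <- withr::local_tempdir()
  py <- Sys.which("python")
  script <- sprintf("
import numpy as np, scipy.io
rng = np.random.default_rng(5)
cube = np.round(rng.uniform(0, 100, (4, 5, 3)), 6)
scipy.io.savemat(r'%s/plain.mat', {'hsdata': cube}, do_compression=False)
scipy.io.savemat(r'%s/comp.mat', {'hsdata': cube, 'other': np.arange(6.0)},
                 do_compression=True)
scipy.io.savemat(r'%s/flat.mat', {'img': np.eye(3)})
np.savetxt(r'%s/cube.txt', cube.reshape(-1, order='F'))
", tmp, tmp, tmp, tmp)
  sf <- file.path(tmp, "gen.py")
  writeLines(script, sf)
  res <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(tmp, "plain.mat")))
  truth <- array(scan(file.path(tmp, "cube.txt"), quiet = TRUE), c(4, 5, 3))
  for (f in c("plain.mat", "comp.mat")) {
    cube <- readCube(file.path(tmp, f), format = "mat", matVar = "hsdata")
    expect_equal(cubeData(cube), truth, tolerance = 1e-12, label = f)
    expect_true(isTRUE(metaData(cube)$syntheticWavelengths))
  }
  # auto-detection of the 3-D variable
  auto <- readCube(file.path(tmp, "comp.mat"), format = "mat")
  expect_equal(dim(auto), c(4, 5, 3))
  # non-3-D payload is rejected
  expect_error(readCube(file.path(tmp, "flat.mat"), format = "mat"),
               "3-D")
})
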