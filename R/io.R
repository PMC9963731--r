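# On-disk formats. ENVI rasters are plain .hdr text + raw binary; HDF5 goes
# through rhdf5; MATLAB v5 import is a minimal reader for numeric arrays.

.enviTypes <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 12L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  name = c("uint8", "int16", "int32", "float32", "float64", "uint16"),
  stringsAsFactors = FALSE
)

.enviHdrPath <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext)) paste0(tools::file_path_sans_ext(path), ".hdr")
  else paste0(path, ".hdr")
}

.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header: ", hdrPath)
  # key = value, where value may be a {...} block spanning lines
  fields <- list()
  pat <- "(?m)^\\s*([a-zA-Z_][a-zA-Z0-9_ ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- m
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
      key <- tolower(trimws(sub("=.*$", "", piece)))
      val <- trimws(sub("^[^=]*=", "", piece))
      if (startsWith(val, "{"))
        val <- trimws(gsub("[{}]", "", gsub("\n", " ", val)))
      fields[[key]] <- val
    }
  }
  fields
}

.readEnvi <- function(path) {
  hdr <- .parseEnviHeader(.enviHdrPath(path))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  W <- as.integer(hdr$samples); H <- as.integer(hdr$lines)
  B <- as.integer(hdr$bands)
  tp <- .enviTypes[.enviTypes$code == as.integer(hdr[["data type"]]), ]
  if (nrow(tp) != 1) stop("unsupported ENVI data type ", hdr[["data type"]])
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1) "big" else "little"
  offset <- if (!is.null(hdr[["header offset"]]))
    as.integer(hdr[["header offset"]]) else 0L
  n <- H * W * B
  expect <- offset + n * tp$size
  if (file.info(path)$size < expect)
    stop(sprintf("ENVI payload too short: header implies %d bytes, file has %d",
                 expect, file.info(path)$size))
  con <- file(path, "rb"); on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
               endian = endian)
  interleave <- tolower(hdr$interleave)
  arr <- switch(interleave,
    bsq = aperm(array(v, c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, c(B, W, H)), c(3, 2, 1)),
    stop("unknown ENVI interleave: ", interleave))
  wl <- NULL
  meta <- list()
  if (!is.null(hdr$wavelength))
    wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  for (k in names(hdr)) {
    if (startsWith(k, "meta_"))
      meta[[substring(k, 6)]] <- hdr[[k]]
  }
  list(data = arr, wavelengths = wl, meta = meta)
}

.writeEnvi <- function(cube, path, interleave = "bsq", dtype = "float32") {
  tp <- .enviTypes[.enviTypes$name == dtype, ]
  if (nrow(tp) != 1) stop("unsupported ENVI dtype: ", dtype)
  d <- dim(cube@data); H <- d[1]; W <- d[2]; B <- d[3]
  interleave <- tolower(interleave)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2, 1, 3))),
    bil = as.vector(aperm(cube@data, c(2, 3, 1))),
    bip = as.vector(aperm(cube@data, c(3, 2, 1))),
    stop("unknown ENVI interleave: ", interleave))
  metaLines <- character(0)
  for (k in names(cube@meta)) {
    val <- cube@meta[[k]]
    if (is.atomic(val) && length(val) == 1)
      metaLines <- c(metaLines, sprintf("meta_%s = %s", k, as.character(val)))
  }
  hdr <- c(
    "ENVI",
    "description = {hsmisr export}",
    sprintf("samples = %d", W),
    sprintf("lines = %d", H),
    sprintf("bands = %d", B),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", tp$code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube@wavelengths, digits = 17, trim = TRUE,
                         scientific = FALSE), collapse = ", ")),
    metaLines
  )
  writeLines(hdr, .enviHdrPath(path))
  con <- file(path, "wb"); on.exit(close(con))
  if (tp$what == "integer")
    writeBin(as.integer(v), con, size = tp$size, endian = "little")
  else if (dtype == "float32")
    writeBin(v, con, size = 4L, endian = "little")
  else
    writeBin(v, con, size = 8L, endian = "little")
  invisible(NULL)
}

.readHdf5 <- function(path) {
  arr <- rhdf5::h5read(path, "data")
  wl <- tryCatch(as.numeric(rhdf5::h5read(path, "wavelengths_nm")),
                 error = function(e) NULL)
  meta <- tryCatch({
    js <- rhdf5::h5read(path, "meta_json")
    jsonlite::fromJSON(as.character(js), simplifyVector = TRUE)
  }, error = function(e) list())
  list(data = arr, wavelengths = wl, meta = as.list(meta))
}

.writeHdf5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube@data, path, "data")
  rhdf5::h5write(cube@wavelengths, path, "wavelengths_nm")
  js <- as.character(jsonlite::toJSON(cube@meta, auto_unbox = TRUE,
                                      digits = NA, null = "null"))
  rhdf5::h5write(js, path, "meta_json")
  rhdf5::h5closeAll()
  invisible(NULL)
}

#' Read a hyperspectral cube from disk
#'
#' Reads ENVI rasters (.hdr sibling required; BSQ/BIL/BIP interleaves are
#' normalised to (row, col, band)), HDF5 containers written by
#' [writeCube()], or MATLAB v5 files (read-only import, e.g. for public
#' cubes). Missing wavelength metadata yields a synthetic 1..B axis and sets
#' \code{meta$syntheticWavelengths}.
#'
#' @param path data file path.
#' @param format one of \code{"envi"}, \code{"hdf5"}, \code{"mat"}.
#' @param matVar for \code{format = "mat"}, name of the variable holding the
#'   cube; defaults to the first numeric 3-D array in the file.
#' @return An \linkS4class{HSCube}.
#' @seealso [writeCube()]
#' @export
readCube <- function(path, format = c("envi", "hdf5", "mat"), matVar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  r <- switch(format,
    envi = .readEnvi(path),
    hdf5 = .readHdf5(path),
    mat = {
      vars <- readMat5(path)
      arr <- if (!is.null(matVar)) {
        if (is.null(vars[[matVar]]))
          stop("variable '", matVar, "' not found in ", path)
        vars[[matVar]]
      } else {
        is3d <- vapply(vars, function(v) length(dim(v)) == 3, logical(1))
        if (!any(is3d)) stop("no 3-D numeric array found in ", path)
        vars[[which(is3d)[1]]]
      }
      list(data = arr, wavelengths = NULL, meta = list(sourceMat = path))
    })
  if (length(dim(r$data)) != 3L)
    stop("payload in ", path, " is not a 3-D cube")
  meta <- r$meta
  meta$source <- path
  HSCube(r$data, wavelengths = r$wavelengths, meta = meta)
}

#' Write a hyperspectral cube to disk
#'
#' ENVI and HDF5 round-trip bit-exactly through [readCube()] for matching
#' data types (use \code{dtype = "float64"} for arbitrary doubles;
#' \code{"float32"} suffices for float32-representable values). Scalar meta
#' entries are preserved (as header strings for ENVI, losslessly as JSON for
#' HDF5).
#'
#' @param cube an \linkS4class{HSCube}.
#' @param path output data file path (ENVI also writes a sibling .hdr).
#' @param format \code{"envi"} or \code{"hdf5"}.
#' @param interleave ENVI interleave, one of \code{"bsq"}, \code{"bil"},
#'   \code{"bip"}.
#' @param dtype ENVI sample type: \code{"uint8"}, \code{"int16"},
#'   \code{"int32"}, \code{"uint16"}, \code{"float32"} or \code{"float64"}.
#' @export
writeCube <- function(cube, path, format = c("envi", "hdf5"),
                      interleave = "bsq", dtype = "float32") {
  stopifnot(is(cube, "HSCube"))
  format <- match.arg(format)
  switch(format,
    envi = .writeEnvi(cube, path, interleave = interleave, dtype = dtype),
    hdf5 = .writeHdf5(cube, path))
  invisible(NULL)
}

#' Export one band as an 8-bit PNG
#'
#' Min-max stretches the band to [0, 255] for visual inspection.
#'
#' @param cube an \linkS4class{HSCube}.
#' @param bandIndex 0-based band index.
#' @param path output PNG path.
#' @export
writeBandPNG <- function(cube, bandIndex, path) {
  img <- selectBand(cube, bandIndex)
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
         else img * 0
  png::writePNG(img, path)
  invisible(NULL)
}
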