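#' Construct a hyperspectral cube
#'
#' @param data numeric 3-D array with axes (row, col, band).
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band. If missing, a synthetic \code{1:B}
#'   axis is used and flagged in \code{meta$syntheticWavelengths}.
#' @param meta named list of provenance entries.
#' @return An \linkS4class{HSCube}.
#' @examples
#' cube <- HSCube(array(runif(4 * 4 * 3), c(4, 4, 3)),
#'                wavelengths = c(500, 600, 700))
#' dim(cube)
#' @export
HSCube <- function(data, wavelengths = NULL, meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  storage.mode(data) <- "double"
  if (is.null(wavelengths)) {
    wavelengths <- as.numeric(seq_len(dim(data)[3]))
    meta$syntheticWavelengths <- TRUE
  }
  new("HSCube", data = data, wavelengths = as.numeric(wavelengths),
      meta = meta)
}

#' @describeIn HSCube construct a reference capture.
#' @param kind \code{"white"} or \code{"dark"}.
#' @export
ReferenceCapture <- function(data, kind = c("white", "dark")) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  new("ReferenceCapture", data = data, kind = match.arg(kind))
}

#' Accessors for hyperspectral containers
#'
#' @param object an \linkS4class{HSCube} or related object.
#' @return \code{cubeData} returns the raw 3-D array; \code{wavelengths} the
#'   wavelength axis in nm; \code{metaData} the provenance list; \code{nBands}
#'   the number of spectral bands.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cubeData", function(object) standardGeneric("cubeData"))

#' @rdname accessors
#' @export
setMethod("cubeData", "HSCube", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "HSCube", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setGeneric("metaData", function(object) standardGeneric("metaData"))

#' @rdname accessors
#' @export
setMethod("metaData", "HSCube", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setMethod("nBands", "HSCube", function(object) dim(object@data)[3])

#' @rdname accessors
#' @param x an \linkS4class{HSCube}.
#' @export
setMethod("dim", "HSCube", function(x) dim(x@data))

setMethod("show", "HSCube", function(object) {
  d <- dim(object@data)
  wl <- object@wavelengths
  cat(sprintf("HSCube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(wl), max(wl)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "LabeledSequence", function(object) {
  d <- dim(object@frames[[1]]@data)
  cat(sprintf(
    "LabeledSequence: %d frames of %d x %d x %d, ef = %d, reference = %d\n",
    length(object@frames), d[1], d[2], d[3], object@ef,
    object@referenceIndex))
})

setMethod("show", "PCABandModel", function(object) {
  cat(sprintf("PCABandModel: %d bands, variance ratio %.3f\n",
              length(object@loadings), object@varianceRatio))
})

setMethod("show", "GlobalMotion", function(object) {
  cat(sprintf(
    "GlobalMotion: (dy, dx) = (%d, %d) quarter-px, %d blocks, agreement %.2f\n",
    object@dyQ, object@dxQ, object@nBlocks, object@agreement))
})

setMethod("show", "HRGrid", function(object) {
  cat(sprintf("HRGrid: %d x %d (ef = %d), %d holes\n",
              nrow(object@weightedSum), ncol(object@weightedSum), object@ef,
              sum(object@weightTotal == 0)))
})

#' Crop a cube spatially
#'
#' Extracts a half-open spatial window \code{[row0, row0 + height) x
#' [col0, col0 + width)} with 0-based offsets, retaining all bands.
#'
#' @param cube an \linkS4class{HSCube}.
#' @param row0,col0 0-based offsets of the window origin.
#' @param height,width window extent in pixels.
#' @return An \linkS4class{HSCube} of shape \code{height x width x B}.
#' @examples
#' cube <- HSCube(array(1:300, c(10, 10, 3)))
#' dim(cropSpatial(cube, 2, 3, 4, 4))
#' @export
cropSpatial <- function(cube, row0, col0, height, width) {
  stopifnot(is(cube, "HSCube"))
  d <- dim(cube@data)
  if (row0 < 0 || col0 < 0 || height < 1 || width < 1 ||
      row0 + height > d[1] || col0 + width > d[2])
    stop(sprintf(
      "crop window [%d,%d) x [%d,%d) outside cube extent %d x %d",
      row0, row0 + height, col0, col0 + width, d[1], d[2]))
  HSCube(cube@data[(row0 + 1):(row0 + height),
                   (col0 + 1):(col0 + width), , drop = FALSE],
         wavelengths = cube@wavelengths, meta = cube@meta)
}

#' Extract one spectral band
#'
#' @param cube an \linkS4class{HSCube}.
#' @param bandIndex 0-based band index.
#' @return An H x W numeric matrix (a copy; mutating it does not alter the
#'   cube).
#' @export
selectBand <- function(cube, bandIndex) {
  stopifnot(is(cube, "HSCube"))
  B <- dim(cube@data)[3]
  if (bandIndex < 0 || bandIndex >= B)
    stop(sprintf("band index %d out of range [0, %d)", bandIndex, B))
  m <- cube@data[, , bandIndex + 1L, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}
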