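#' @import methods
NULL

#' Hyperspectral cube
#'
#' The universal data currency of the package: an H x W x B intensity volume
#' with axes (row, col, band) and a strictly increasing wavelength axis.
#' Raw sensor cubes may hold integers; calibrated cubes hold non-negative
#' reals. Arbitrary provenance (source file, calibration state, escalation
#' factor, ...) travels in the \code{meta} list.
#'
#' @slot data numeric 3-D array, axes (row, col, band).
#' @slot wavelengths numeric vector of length \code{dim(data)[3]}, strictly
#'   increasing, in nanometres.
#' @slot meta named list of free-form provenance entries.
#'
#' @seealso [HSCube()] for the user-facing constructor, [readCube()],
#'   [cropSpatial()], [selectBand()].
#' @export
setClass("HSCube",
  representation(data = "array", wavelengths = "numeric", meta = "list"),
  prototype(data = array(0, c(1, 1, 1)), wavelengths = 1, meta = list())
)

setValidity("HSCube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must have exactly 3 axes (row, col, band)")
  if (dim(d)[3] != length(object@wavelengths))
    return("band-axis length must equal length(wavelengths)")
  if (anyNA(d) || any(is.infinite(d)))
    return("data must not contain NaN/NA/Inf")
  wl <- object@wavelengths
  if (any(wl <= 0) || anyNA(wl))
    return("wavelengths must be positive reals")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Multi-line reference capture (white or dark)
#'
#' A push-broom reference capture of L scan lines x W pixels x B bands,
#' taken either of the bare light source (\code{kind = "white"}) or with the
#' shutter closed (\code{kind = "dark"}). Collapsed by [collapseReference()]
#' to the single averaged line used by [calibrateCube()].
#'
#' @slot data numeric 3-D array, axes (line, col, band).
#' @slot kind either \code{"white"} or \code{"dark"}.
#' @export
setClass("ReferenceCapture",
  representation(data = "array", kind = "character"),
  prototype(data = array(0, c(1, 1, 1)), kind = "dark")
)

setValidity("ReferenceCapture", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-D array (line, col, band)")
  if (dim(d)[1] < 1L) return("at least one scan line required")
  if (!object@kind %in% c("white", "dark"))
    return("kind must be 'white' or 'dark'")
  if (anyNA(d) || any(is.infinite(d))) return("data must be finite")
  TRUE
})

#' Averaged 1-line calibration reference
#'
#' The per-column, per-band mean over the scan lines of a
#' \linkS4class{ReferenceCapture}; one such white line and one dark line
#' calibrate every scan row of a raw cube.
#'
#' @slot data numeric 1 x W x B array.
#' @slot kind either \code{"white"} or \code{"dark"}.
#' @slot nLinesAveraged number of scan lines that were averaged.
#' @export
setClass("ReferenceLine",
  representation(data = "array", kind = "character", nLinesAveraged = "integer"),
  prototype(data = array(0, c(1, 1, 1)), kind = "dark", nLinesAveraged = 1L)
)

setValidity("ReferenceLine", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L || dim(d)[1] != 1L)
    return("data must be a 1 x W x B array")
  if (!object@kind %in% c("white", "dark"))
    return("kind must be 'white' or 'dark'")
  if (object@nLinesAveraged < 1L) return("nLinesAveraged must be >= 1")
  TRUE
})

#' Labelled low-resolution frame sequence
#'
#' A list of equally shaped low-resolution \linkS4class{HSCube} frames, each
#' tagged with its true (or estimated) global displacement relative to the
#' reference frame, in quarter-pixel units at the LR scale (4 units = 1 LR
#' pixel). Labels store the content motion of the frame relative to the
#' reference: a scene shifted by +k HR pixels appears as a label of
#' -k*4/ef quarter-units.
#'
#' @slot frames list of \linkS4class{HSCube}, all sharing shape and
#'   wavelengths.
#' @slot labels integer matrix, one row per frame, columns (dy_q, dx_q).
#' @slot ef integer pooling/escalation factor, 2 or 4.
#' @slot referenceIndex 1-based index of the reference frame; its label is
#'   (0, 0).
#' @export
setClass("LabeledSequence",
  representation(frames = "list", labels = "matrix", ef = "integer",
                 referenceIndex = "integer"),
  prototype(frames = list(), labels = matrix(0L, 0, 2), ef = 2L,
            referenceIndex = 1L)
)

setValidity("LabeledSequence", function(object) {
  n <- length(object@frames)
  if (n < 1L) return("at least one frame required")
  if (!all(vapply(object@frames, is, logical(1), "HSCube")))
    return("all frames must be HSCube objects")
  if (!is.integer(object@labels) || nrow(object@labels) != n ||
      ncol(object@labels) != 2L)
    return("labels must be an integer n x 2 matrix (dy_q, dx_q)")
  if (!object@ef %in% c(2L, 4L)) return("ef must be 2 or 4")
  ri <- object@referenceIndex
  if (ri < 1L || ri > n) return("referenceIndex out of range")
  if (any(object@labels[ri, ] != 0L))
    return("reference frame label must be (0, 0)")
  d0 <- dim(object@frames[[1]]@data)
  for (f in object@frames) {
    if (!identical(dim(f@data), d0))
      return("all frames must share the same shape")
    if (!identical(f@wavelengths, object@frames[[1]]@wavelengths))
      return("all frames must share the same wavelengths")
  }
  TRUE
})

#' First-principal-component band model
#'
#' Unit-norm loadings and mean spectrum fitted on a reference cube; projects
#' any cube with a matching band count to a single high-variance synthetic
#' band on which block matching is run.
#'
#' @slot loadings numeric length-B vector, unit Euclidean norm.
#' @slot meanSpectrum numeric length-B vector.
#' @slot varianceRatio fraction of total spectral variance captured by the
#'   first component, in [0, 1].
#' @export
setClass("PCABandModel",
  representation(loadings = "numeric", meanSpectrum = "numeric",
                 varianceRatio = "numeric"),
  prototype(loadings = 1, meanSpectrum = 0, varianceRatio = 1)
)

setValidity("PCABandModel", function(object) {
  if (length(object@loadings) != length(object@meanSpectrum))
    return("loadings and meanSpectrum must have the same length")
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-9)
    return("loadings must have unit norm")
  vr <- object@varianceRatio
  if (vr < 0 || vr > 1 + 1e-12) return("varianceRatio must lie in [0, 1]")
  TRUE
})

#' Global frame motion
#'
#' A single whole-frame displacement in quarter-pixel units, aggregated from
#' the per-macroblock motion field, with diagnostics.
#'
#' @slot dyQ,dxQ integer displacement components, quarter-pixel units.
#' @slot nBlocks number of macroblocks that voted (non-flat blocks).
#' @slot agreement fraction of voting macroblocks whose vector equals the
#'   global one, in [0, 1].
#' @export
setClass("GlobalMotion",
  representation(dyQ = "integer", dxQ = "integer", nBlocks = "integer",
                 agreement = "numeric"),
  prototype(dyQ = 0L, dxQ = 0L, nBlocks = 0L, agreement = 1)
)

setValidity("GlobalMotion", function(object) {
  if (object@agreement < 0 || object@agreement > 1)
    return("agreement must lie in [0, 1]")
  TRUE
})

#' High-resolution accumulator grid
#'
#' The shift-and-add accumulator for one band: weighted sums and weight
#' totals on the EF-upscaled grid. Cells with zero weight are holes, filled
#' afterwards by [fillHoles()].
#'
#' @slot weightedSum numeric matrix, H*ef x W*ef.
#' @slot weightTotal numeric matrix of the same shape, non-negative.
#' @slot ef integer escalation factor.
#' @export
setClass("HRGrid",
  representation(weightedSum = "matrix", weightTotal = "matrix",
                 ef = "integer"),
  prototype(weightedSum = matrix(0, 1, 1), weightTotal = matrix(0, 1, 1),
            ef = 2L)
)

setValidity("HRGrid", function(object) {
  if (!identical(dim(object@weightedSum), dim(object@weightTotal)))
    return("weightedSum and weightTotal must share a shape")
  if (any(object@weightTotal < 0)) return("weightTotal must be >= 0")
  if (any(object@weightedSum[object@weightTotal == 0] != 0))
    return("weightedSum must be 0 wherever weightTotal is 0")
  TRUE
})
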