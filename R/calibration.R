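# White/dark reference calibration of raw push-broom cubes. Because the
# second spatial axis of a push-broom cube comes from stage motion, one
# averaged reference line per (column, band) calibrates every scan row.

#' Collapse a multi-line reference capture to its averaged line
#'
#' Averages the L scan lines of a white or dark reference capture per
#' (column, band), producing the single 1 x W x B line used for
#' calibration.
#'
#' @param capture a \linkS4class{ReferenceCapture}.
#' @return A \linkS4class{ReferenceLine}.
#' @export
collapseReference <- function(capture) {
  stopifnot(is(capture, "ReferenceCapture"))
  d <- dim(capture@data)
  if (d[1] < 1L) stop("reference capture has no scan lines")
  line <- colMeans(capture@data)          # W x B means over lines
  new("ReferenceLine", data = array(line, c(1L, d[2], d[3])),
      kind = capture@kind, nLinesAveraged = d[1])
}

#' Calibrate a raw cube against white and dark reference lines
#'
#' Applies the flat-field normalisation
#' \deqn{CI = (RI - DR) / (WR - DR)}
#' per pixel and band, broadcasting the averaged 1-line references to every
#' scan row. Denominators below \code{denomFloor} are floored (and counted in
#' \code{meta$flooredDenominators}); negative calibrated values, which can
#' arise from sensor noise, are clipped to 0 and counted in
#' \code{meta$clippedNegative}. Values above 1 are left untouched.
#'
#' @param raw an \linkS4class{HSCube} of raw sensor intensities.
#' @param white,dark \linkS4class{ReferenceLine}s with matching W and B.
#' @param denomFloor smallest admissible denominator; default 1e-6 of the
#'   white line's dynamic range.
#' @return A calibrated \linkS4class{HSCube}; \code{meta$calibrated} is set.
#' @export
calibrateCube <- function(raw, white, dark, denomFloor = NULL) {
  stopifnot(is(raw, "HSCube"), is(white, "ReferenceLine"),
            is(dark, "ReferenceLine"))
  if (white@kind != "white" || dark@kind != "dark")
    stop("white/dark arguments have the wrong reference kind")
  d <- dim(raw@data)
  dw <- dim(white@data); dd <- dim(dark@data)
  if (!identical(dw[2:3], d[2:3]) || !identical(dd[2:3], d[2:3]))
    stop(sprintf(
      "shape mismatch: raw is %d x %d x %d but references are W=%d/%d, B=%d/%d",
      d[1], d[2], d[3], dw[2], dd[2], dw[3], dd[3]))
  wr <- array(white@data, dw[2:3])        # W x B
  dr <- array(dark@data, dd[2:3])
  denom <- wr - dr
  if (is.null(denomFloor)) {
    dynRange <- diff(range(wr))
    denomFloor <- if (dynRange > 0) 1e-6 * dynRange else 1e-12
  }
  floored <- denom < denomFloor
  if (all(floored))
    stop("white and dark references coincide everywhere; calibration is meaningless")
  denom[floored] <- denomFloor
  H <- d[1]
  # broadcast the 1-line references across scan rows
  num <- raw@data - rep(dr, each = H)
  out <- num / rep(denom, each = H)
  clipped <- out < 0
  out[clipped] <- 0
  meta <- raw@meta
  meta$calibrated <- TRUE
  meta$flooredDenominators <- sum(floored)
  meta$clippedNegative <- sum(clipped)
  HSCube(out, wavelengths = raw@wavelengths, meta = meta)
}
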