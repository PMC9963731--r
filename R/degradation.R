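# Observation-model simulator: degrades a high-resolution cube into labelled
# low-resolution sequences by window selection + box average pooling, the
# same forward model assumed by the shift-and-add reconstruction.

#' Box average pooling
#'
#' Replaces each factor x factor block by its arithmetic mean.
#'
#' @param image numeric matrix with both dimensions divisible by
#'   \code{factor}.
#' @param factor pooling factor (e.g. 2 or 4).
#' @return Matrix of shape \code{nrow/factor x ncol/factor}.
#' @export
averagePool <- function(image, factor) {
  h <- nrow(image); w <- ncol(image)
  factor <- as.integer(factor)
  if (factor < 1L) stop("pooling factor must be >= 1")
  if (h %% factor != 0L || w %% factor != 0L)
    stop(sprintf("image %d x %d not divisible by pooling factor %d",
                 h, w, factor))
  poolRows <- function(m, f) {
    matrix(colSums(matrix(m, nrow = f)), nrow = nrow(m) %/% f) / f
  }
  t(poolRows(t(poolRows(image, factor)), factor))
}

#' Deterministic sub-pixel shift pattern
#'
#' Returns \code{n} integer HR-pixel offsets starting at (0,0), walking
#' outward in square rings (clockwise from the east neighbour) and picking,
#' first, one representative of each of the ef^2 distinct sub-pixel phases
#' (offset mod ef) at 1- and 2-pixel distances; once all phases are covered
#' the skipped ring offsets, and then larger rings, fill up the sequence, so
#' phases repeat at larger integer offsets.
#'
#' @param ef pooling factor, 2 or 4.
#' @param n number of offsets.
#' @return n x 2 integer matrix of (dy_hr, dx_hr) offsets.
#' @export
defaultShiftPattern <- function(ef, n) {
  ef <- as.integer(ef)
  if (!ef %in% c(2L, 4L)) stop("ef must be 2 or 4")
  if (n < 1L) stop("n must be >= 1")
  ringOffsets <- function(r) {
    if (r == 0L) return(matrix(0L, 1, 2))
    # clockwise perimeter walk starting at (0, r)
    path <- rbind(
      cbind(0:r, r),                                   # east edge, going south
      cbind(r, (r - 1):(-r)),                          # south edge, going west
      cbind((r - 1):(-r), -r),                         # west edge, going north
      cbind(-r, (-r + 1):r),                           # north edge, going east
      if (r > 1L) cbind((-r + 1):(-1L), r) else NULL   # back up the east edge
    )
    storage.mode(path) <- "integer"
    path
  }
  candidates <- do.call(rbind, lapply(0:2, ringOffsets))
  phase <- function(o) paste(o[1] %% ef, o[2] %% ef)
  seen <- character(0)
  picked <- integer(0)
  for (i in seq_len(nrow(candidates))) {         # phase-first pass
    p <- phase(candidates[i, ])
    if (!p %in% seen) { seen <- c(seen, p); picked <- c(picked, i) }
    if (length(seen) == ef * ef) break
  }
  order <- c(picked, setdiff(seq_len(nrow(candidates)), picked))
  offsets <- candidates[order, , drop = FALSE]
  r <- 3L
  while (nrow(offsets) < n) {                    # extend with larger rings
    offsets <- rbind(offsets, ringOffsets(r))
    r <- r + 1L
  }
  out <- offsets[seq_len(n), , drop = FALSE]
  colnames(out) <- c("dy_hr", "dx_hr")
  out
}

#' Generate a labelled low-resolution sequence from an HR cube
#'
#' Emulates capturing the same scene at integer HR-pixel offsets: the anchor
#' window is the very-high-resolution reference (VHRI); each frame is the
#' per-band \code{ef x ef} average pooling of the window displaced by its
#' shift. The true motion label of frame i is \code{-shift_i * 4 / ef} in
#' quarter-pixel units: a scene shifted by +1 HR pixel appears as content
#' motion of -1/ef LR pixel of the frame relative to the reference, so a
#' 1-pixel stage move becomes a half-pixel (ef = 2) or quarter-pixel
#' (ef = 4) frame motion.
#'
#' @param cube source \linkS4class{HSCube}.
#' @param anchorRow,anchorCol 0-based origin of the reference window.
#' @param size window side length; must be divisible by \code{ef}.
#' @param shifts n x 2 integer matrix (or list of length-2 vectors) of HR
#'   offsets; the first must be (0, 0).
#' @param ef pooling factor, 2 or 4.
#' @return List with elements \code{vhri} (the anchor crop, all bands) and
#'   \code{seq} (a \linkS4class{LabeledSequence}). Duplicate shifts are
#'   allowed but flagged in the reference frame's meta.
#' @export
generateSequence <- function(cube, anchorRow, anchorCol, size, shifts, ef) {
  stopifnot(is(cube, "HSCube"))
  ef <- as.integer(ef)
  if (!ef %in% c(2L, 4L)) stop("ef must be 2 or 4")
  if (size %% ef != 0L) stop("size must be divisible by ef")
  if (is.list(shifts)) shifts <- do.call(rbind, shifts)
  shifts <- matrix(as.integer(shifts), ncol = 2)
  if (any(shifts[1, ] != 0L)) stop("shifts[1, ] must be (0, 0)")
  d <- dim(cube@data)
  vhri <- cropSpatial(cube, anchorRow, anchorCol, size, size)
  duplicated <- anyDuplicated(shifts) > 0
  frames <- vector("list", nrow(shifts))
  labels <- matrix(0L, nrow(shifts), 2)
  for (i in seq_len(nrow(shifts))) {
    r0 <- anchorRow + shifts[i, 1]; c0 <- anchorCol + shifts[i, 2]
    if (r0 < 0 || c0 < 0 || r0 + size > d[1] || c0 + size > d[2])
      stop(sprintf("shift (%d, %d) drives the window out of bounds",
                   shifts[i, 1], shifts[i, 2]))
    crop <- cropSpatial(cube, r0, c0, size, size)
    lr <- array(0, c(size %/% ef, size %/% ef, d[3]))
    for (b in seq_len(d[3]))
      lr[, , b] <- averagePool(crop@data[, , b], ef)
    meta <- list(shiftHR = shifts[i, ])
    if (i == 1 && duplicated) meta$duplicateShifts <- TRUE
    frames[[i]] <- HSCube(lr, wavelengths = cube@wavelengths, meta = meta)
    labels[i, ] <- -shifts[i, ] * 4L %/% ef
  }
  seq <- new("LabeledSequence", frames = frames, labels = labels, ef = ef,
             referenceIndex = 1L)
  list(vhri = vhri, seq = seq)
}

#' Persist a labelled sequence to a directory
#'
#' Writes one HDF5 cube per frame plus a \code{sequence.json} manifest
#' holding the frame file names, quarter-pixel labels, ef and the reference
#' index (0-based in the manifest).
#'
#' @param seq a \linkS4class{LabeledSequence}.
#' @param dir output directory (created if missing).
#' @export
writeSequence <- function(seq, dir) {
  stopifnot(is(seq, "LabeledSequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq@frames)
  files <- sprintf("frame_%03d.h5", seq_len(n) - 1L)
  for (i in seq_len(n))
    writeCube(seq@frames[[i]], file.path(dir, files[i]), format = "hdf5")
  manifest <- list(
    frames = files,
    labels_quarter_px = unname(apply(seq@labels, 1, as.list)),
    ef = seq@ef,
    reference_index = seq@referenceIndex - 1L
  )
  jsonlite::write_json(manifest, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a labelled sequence written by [writeSequence()]
#'
#' @param dir directory holding \code{sequence.json} and the frame files.
#' @return A \linkS4class{LabeledSequence}.
#' @export
readSequence <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "sequence.json"),
                                  simplifyVector = TRUE)
  frames <- lapply(manifest$frames,
                   function(f) readCube(file.path(dir, f), format = "hdf5"))
  lab <- manifest$labels_quarter_px
  labels <- if (is.matrix(lab)) {
    matrix(as.integer(lab), nrow(lab), 2)
  } else {
    matrix(as.integer(unlist(lab)), ncol = 2, byrow = TRUE)
  }
  new("LabeledSequence", frames = frames, labels = labels,
      ef = as.integer(manifest$ef),
      referenceIndex = as.integer(manifest$reference_index) + 1L)
}
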