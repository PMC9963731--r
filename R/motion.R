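# Fusion planning: one synthetic high-variance band per frame via the
# reference cube's first principal component, then per-macroblock full-search
# block matching with SAD, refined to half- then quarter-pixel precision by
# bilinear resampling, and aggregated to a single global motion per frame.

#' Fit a first-principal-component band model on a reference cube
#'
#' Mean-centres the pixels x bands matrix and takes the first right singular
#' vector as loadings; the variance ratio is the leading eigenvalue over the
#' trace of the spectral covariance. The sign is fixed so the
#' largest-magnitude loading is positive. A warning (not an error) is
#' emitted when the first component captures less than 65% of the variance,
#' the level found sufficient for sub-pixel motion estimation on pathology
#' imagery.
#'
#' @param reference an \linkS4class{HSCube} with at least 2 spatial pixels.
#' @return A \linkS4class{PCABandModel}.
#' @export
fitPCABand <- function(reference) {
  stopifnot(is(reference, "HSCube"))
  d <- dim(reference@data)
  if (d[1] * d[2] < 2) stop("need at least 2 spatial pixels")
  X <- matrix(reference@data, d[1] * d[2], d[3])
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  totalVar <- sum(Xc^2) / (nrow(Xc) - 1)
  if (totalVar <= 0)
    stop("cube has zero spectral variance; motion estimation impossible on flat input")
  sv <- svd(Xc, nu = 0, nv = 1)
  loadings <- sv$v[, 1]
  i <- which.max(abs(loadings))
  if (loadings[i] < 0) loadings <- -loadings
  vr <- (sv$d[1]^2 / (nrow(Xc) - 1)) / totalVar
  if (vr < 0.65)
    warning(sprintf(
      "first principal component captures only %.1f%% of the variance (< 65%%)",
      100 * vr))
  new("PCABandModel", loadings = loadings, meanSpectrum = mu,
      varianceRatio = min(vr, 1))
}

#' Project a cube onto a fitted band model
#'
#' Pixelwise dot product of the mean-centred spectrum with the loadings; the
#' reference model is reused unchanged for every frame of a sequence.
#'
#' @param cube an \linkS4class{HSCube} with the model's band count.
#' @param model a \linkS4class{PCABandModel}.
#' @return An H x W numeric matrix.
#' @export
projectBand <- function(cube, model) {
  stopifnot(is(cube, "HSCube"), is(model, "PCABandModel"))
  d <- dim(cube@data)
  if (d[3] != length(model@loadings))
    stop(sprintf("cube has %d bands but the model expects %d",
                 d[3], length(model@loadings)))
  X <- matrix(cube@data, d[1] * d[2], d[3])
  matrix(sweep(X, 2, model@meanSpectrum) %*% model@loadings, d[1], d[2])
}

#' Sum of absolute differences between two blocks
#'
#' @param blockA,blockB numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
sadCost <- function(blockA, blockB) {
  if (!identical(dim(blockA), dim(blockB)))
    stop("blocks must have the same shape")
  sum(abs(blockA - blockB))
}

# bilinear sample of img at fractional (y, x) coordinate matrices (1-based);
# all coordinates must satisfy 1 <= y <= nrow, 1 <= x <= ncol.
.bilinearSample <- function(img, y, x) {
  y0 <- pmin(floor(y), nrow(img) - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(x), ncol(img) - 1L); x0 <- pmax(x0, 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i10 <- cbind(as.vector(y0 + 1L), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0 + 1L))
  i11 <- cbind(as.vector(y0 + 1L), as.vector(x0 + 1L))
  v <- (1 - fy) * (1 - fx) * img[i00] + fy * (1 - fx) * img[i10] +
       (1 - fy) * fx * img[i01] + fy * fx * img[i11]
  matrix(v, nrow(y), ncol(y))
}

.isFlatBlock <- function(block, imageDynRange) {
  stats::var(as.vector(block)) < 1e-12 * max(imageDynRange^2, .Machine$double.eps)
}

#' Full-search integer block matching
#'
#' Exhaustively evaluates all integer displacements in
#' \code{[-searchRange, +searchRange]^2} of the reference block inside the
#' target image, skipping candidates whose window exits the target. Ties are
#' broken by the smaller Euclidean displacement norm, then row-major (dy,
#' dx) order. Flat (untextured) blocks are flagged low-confidence.
#'
#' @param block reference macroblock (numeric matrix).
#' @param blockOrigin length-2 integer, 0-based (row, col) origin of the
#'   block in the reference image.
#' @param target target image (numeric matrix).
#' @param searchRange maximum displacement in LR pixels.
#' @return A list (class \code{MacroblockMatch}) with fields
#'   \code{blockRow}, \code{blockCol}, \code{dyQ}, \code{dxQ} (quarter-pixel
#'   units), \code{sad}, \code{lowConfidence}.
#' @export
fsbmInteger <- function(block, blockOrigin, target, searchRange) {
  bh <- nrow(block); bw <- ncol(block)
  oy <- as.integer(blockOrigin[1]); ox <- as.integer(blockOrigin[2])
  best <- NULL
  for (dy in -searchRange:searchRange) {
    r0 <- oy + dy
    if (r0 < 0 || r0 + bh > nrow(target)) next
    for (dx in -searchRange:searchRange) {
      c0 <- ox + dx
      if (c0 < 0 || c0 + bw > ncol(target)) next
      s <- sum(abs(block - target[(r0 + 1):(r0 + bh), (c0 + 1):(c0 + bw)]))
      n2 <- dy * dy + dx * dx
      if (is.null(best) || s < best$sad ||
          (s == best$sad && n2 < best$n2))
        best <- list(sad = s, dy = dy, dx = dx, n2 = n2)
    }
  }
  if (is.null(best))
    stop("no valid candidate position for block at (", oy, ", ", ox, ")")
  dynRange <- diff(range(target))
  structure(list(blockRow = oy, blockCol = ox,
                 dyQ = 4L * best$dy, dxQ = 4L * best$dx, sad = best$sad,
                 lowConfidence = .isFlatBlock(block, dynRange)),
            class = "MacroblockMatch")
}

# evaluate SAD of `block` against target sampled at fractional displacement
# (dyQ, dxQ) quarter-pixel units from the block origin; NA if out of bounds.
.sadAtQuarter <- function(block, oy, ox, target, dyQ, dxQ) {
  bh <- nrow(block); bw <- ncol(block)
  y <- oy + dyQ / 4 + matrix(seq_len(bh), bh, bw)
  x <- ox + dxQ / 4 + matrix(seq_len(bw), bh, bw, byrow = TRUE)
  if (min(y) < 1 || max(y) > nrow(target) ||
      min(x) < 1 || max(x) > ncol(target)) return(NA_real_)
  sum(abs(block - .bilinearSample(target, y, x)))
}

#' Refine an integer match to quarter-pixel precision
#'
#' Two refinement rounds around the integer winner: the 8 half-pixel
#' neighbours (target resampled bilinearly at fractional coordinates), then
#' the 8 quarter-pixel neighbours of that winner. The SAD is non-increasing
#' across rounds; ties keep the smaller-norm, then row-major candidate.
#'
#' @param match result of [fsbmInteger()].
#' @param block the same reference macroblock.
#' @param target the same target image.
#' @return An updated \code{MacroblockMatch} with quarter-pixel \code{dyQ},
#'   \code{dxQ}.
#' @export
refineSubpixel <- function(match, block, target) {
  if (match$lowConfidence) return(match)
  oy <- match$blockRow; ox <- match$blockCol
  best <- list(dyQ = match$dyQ, dxQ = match$dxQ, sad = match$sad)
  for (stepQ in c(2L, 1L)) {            # half-pixel, then quarter-pixel
    cand <- best
    for (ddy in c(-stepQ, 0L, stepQ)) {
      for (ddx in c(-stepQ, 0L, stepQ)) {
        if (ddy == 0L && ddx == 0L) next
        dyQ <- best$dyQ + ddy; dxQ <- best$dxQ + ddx
        s <- .sadAtQuarter(block, oy, ox, target, dyQ, dxQ)
        if (is.na(s)) next
        better <- s < cand$sad ||
          (s == cand$sad &&
           dyQ^2 + dxQ^2 < cand$dyQ^2 + cand$dxQ^2)
        if (better) cand <- list(dyQ = dyQ, dxQ = dxQ, sad = s)
      }
    }
    best <- cand
  }
  match$dyQ <- best$dyQ; match$dxQ <- best$dxQ; match$sad <- best$sad
  match
}

# round to nearest integer with exact .5 ties toward zero
.roundTiesToZero <- function(x) {
  r <- trunc(x)
  frac <- abs(x - r)
  r + ifelse(frac > 0.5, sign(x), 0)
}

#' Estimate the global motion between two synthetic-band images
#'
#' Partitions the reference band into non-overlapping macroblocks (partial
#' border blocks dropped), matches each into the frame band with
#' [fsbmInteger()] + [refineSubpixel()], and aggregates non-flat block
#' vectors by the componentwise median, rounded to the nearest quarter-unit
#' with ties toward zero. Because the scene undergoes a single global
#' translation, the median is a robust reconciliation of the block field.
#'
#' @param frameBand synthetic band of the frame under estimation.
#' @param refBand synthetic band of the reference frame (same shape).
#' @param mbSize macroblock side length in LR pixels (default 16).
#' @param searchRange integer search radius in LR pixels (default 4).
#' @return A list with \code{global} (a \linkS4class{GlobalMotion}) and
#'   \code{blocks} (a data.frame of per-macroblock matches).
#' @export
estimateGlobalMotion <- function(frameBand, refBand, mbSize = 16L,
                                 searchRange = 4L) {
  if (!identical(dim(frameBand), dim(refBand)))
    stop("frame and reference bands must share a shape")
  h <- nrow(refBand); w <- ncol(refBand)
  nbr <- h %/% mbSize; nbc <- w %/% mbSize
  if (nbr < 1 || nbc < 1) stop("image smaller than one macroblock")
  # centre the block grid so border blocks keep headroom for fractional
  # (half/quarter-pixel) sampling near the image edge
  oy0 <- (h - nbr * mbSize) %/% 2L
  ox0 <- (w - nbc * mbSize) %/% 2L
  matches <- list()
  for (i in seq_len(nbr) - 1L) {
    for (j in seq_len(nbc) - 1L) {
      oy <- oy0 + i * mbSize; ox <- ox0 + j * mbSize
      block <- refBand[(oy + 1):(oy + mbSize), (ox + 1):(ox + mbSize)]
      m <- fsbmInteger(block, c(oy, ox), frameBand, searchRange)
      m <- refineSubpixel(m, block, frameBand)
      matches[[length(matches) + 1L]] <- m
    }
  }
  blocks <- data.frame(
    blockRow = vapply(matches, `[[`, integer(1), "blockRow"),
    blockCol = vapply(matches, `[[`, integer(1), "blockCol"),
    dyQ = vapply(matches, `[[`, integer(1), "dyQ"),
    dxQ = vapply(matches, `[[`, integer(1), "dxQ"),
    sad = vapply(matches, `[[`, numeric(1), "sad"),
    lowConfidence = vapply(matches, `[[`, logical(1), "lowConfidence")
  )
  voting <- blocks[!blocks$lowConfidence, , drop = FALSE]
  if (nrow(voting) == 0)
    stop("untextured frame: all macroblocks are flat")
  gy <- as.integer(.roundTiesToZero(stats::median(voting$dyQ)))
  gx <- as.integer(.roundTiesToZero(stats::median(voting$dxQ)))
  agreement <- mean(voting$dyQ == gy & voting$dxQ == gx)
  global <- new("GlobalMotion", dyQ = gy, dxQ = gx,
                nBlocks = nrow(voting), agreement = agreement)
  list(global = global, blocks = blocks)
}

#' Estimate global motion for every frame of a sequence
#'
#' Fits the principal-component band model on the reference frame, projects
#' every frame through the same model, and runs [estimateGlobalMotion()] per
#' non-reference frame. Also returns the normalised per-frame matching cost
#' used as the deposit weight by [shiftAndAddBand()]: the mean winning SAD
#' over voting blocks divided by (mbSize^2 times the reference band's
#' dynamic range), clipped to [0, 1]; the reference frame's cost is 0.
#'
#' @param seq a \linkS4class{LabeledSequence}.
#' @param mbSize,searchRange see [estimateGlobalMotion()].
#' @return A list with \code{motions} (list of \linkS4class{GlobalMotion}),
#'   \code{sadsNorm} (numeric vector), \code{model} (the
#'   \linkS4class{PCABandModel}) and \code{blocks} (per-frame diagnostics).
#' @export
estimateSequenceMotion <- function(seq, mbSize = 16L, searchRange = 4L) {
  stopifnot(is(seq, "LabeledSequence"))
  ri <- seq@referenceIndex
  model <- fitPCABand(seq@frames[[ri]])
  refBand <- projectBand(seq@frames[[ri]], model)
  dynRange <- max(diff(range(refBand)), .Machine$double.eps)
  n <- length(seq@frames)
  motions <- vector("list", n)
  sadsNorm <- numeric(n)
  blocks <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == ri) {
      motions[[k]] <- new("GlobalMotion", dyQ = 0L, dxQ = 0L,
                          nBlocks = 0L, agreement = 1)
      sadsNorm[k] <- 0
      next
    }
    band <- projectBand(seq@frames[[k]], model)
    est <- estimateGlobalMotion(band, refBand, mbSize, searchRange)
    motions[[k]] <- est$global
    voting <- est$blocks[!est$blocks$lowConfidence, , drop = FALSE]
    sadsNorm[k] <- min(1, mean(voting$sad) / (mbSize^2 * dynRange))
    blocks[[k]] <- est$blocks
  }
  list(motions = motions, sadsNorm = sadsNorm, model = model,
       blocks = blocks)
}

#' Turn a sequence's ground-truth labels into GlobalMotion objects
#'
#' Oracle mode: bypasses estimation and fuses with the simulator's true
#' quarter-pixel labels.
#'
#' @param seq a \linkS4class{LabeledSequence}.
#' @return List of \linkS4class{GlobalMotion}, one per frame.
#' @export
motionsFromLabels <- function(seq) {
  stopifnot(is(seq, "LabeledSequence"))
  lapply(seq_len(nrow(seq@labels)), function(k)
    new("GlobalMotion", dyQ = seq@labels[k, 1], dxQ = seq@labels[k, 2],
        nBlocks = 0L, agreement = 1))
}
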