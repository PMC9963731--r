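# Full-reference quality metrics: SSIM (global-statistics and the standard
# 11x11 Gaussian-window local form), PSNR, the spectral angle mapper, and
# the two composite quality/runtime scores used to rank super-resolution
# methods.

#' SSIM parameters
#'
#' @param k1,k2 stabilisation constants of the SSIM formula (defaults 0.01
#'   and 0.03); C1 = (k1*L)^2, C2 = (k2*L)^2.
#' @param dynamicRangeL dynamic range L of the pixel values (255 for 8-bit;
#'   for calibrated float cubes the evaluator defaults to the reference
#'   band's max - min).
#' @param window \code{"gaussian11"} (the standard 11 x 11 Gaussian local
#'   window, sigma 1.5, averaged over the valid map) or \code{"global"}
#'   (whole-image statistics, evaluated once).
#' @return A named list of class \code{SSIMParams}.
#' @export
ssimParams <- function(k1 = 0.01, k2 = 0.03, dynamicRangeL = 1,
                       window = c("gaussian11", "global")) {
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive")
  if (dynamicRangeL <= 0) stop("dynamicRangeL must be positive")
  structure(list(k1 = k1, k2 = k2, dynamicRangeL = dynamicRangeL,
                 window = match.arg(window)),
            class = "SSIMParams")
}

# separable valid-region Gaussian filtering: K %*% X %*% t(K) with banded K
.gaussValidFilter <- function(x, win = 11L, sigma = 1.5) {
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  band <- function(n) {
    nOut <- n - win + 1L
    K <- matrix(0, nOut, n)
    for (i in seq_len(nOut)) K[i, i:(i + win - 1L)] <- g
    K
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Structural similarity index
#'
#' For \code{window = "global"}, evaluates the SSIM formula once with
#' whole-image means, variances (denominator n - 1) and covariance. For
#' \code{window = "gaussian11"}, computes the standard local SSIM map with
#' an 11 x 11 Gaussian window (sigma 1.5, weighted local statistics, valid
#' region) and returns its mean. Symmetric in its arguments and bounded
#' above by 1.
#'
#' @param x,y numeric matrices of identical shape.
#' @param params an \code{SSIMParams} bundle (see [ssimParams()]).
#' @return Scalar SSIM value.
#' @export
ssim <- function(x, y, params = ssimParams()) {
  if (!identical(dim(x), dim(y))) stop("images must share a shape")
  L <- params$dynamicRangeL
  if (L <= 0) stop("dynamic range L must be positive")
  C1 <- (params$k1 * L)^2
  C2 <- (params$k2 * L)^2
  if (params$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
    cxy <- stats::cov(as.vector(x), as.vector(y))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
           ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  if (nrow(x) < 11 || ncol(x) < 11)
    stop("gaussian11 window requires images of at least 11 x 11")
  mx <- .gaussValidFilter(x); my <- .gaussValidFilter(y)
  xx <- .gaussValidFilter(x * x); yy <- .gaussValidFilter(y * y)
  xy <- .gaussValidFilter(x * y)
  vx <- xx - mx^2; vy <- yy - my^2
  cxy <- xy - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(R^2 / MSE)} in dB; identical images (MSE = 0) return the
#' \code{Inf} sentinel, which [evaluateCubes()] excludes from averages.
#'
#' @param x,y numeric matrices of identical shape.
#' @param R maximum fluctuation of the image data type (e.g. 255 for
#'   8-bit).
#' @return PSNR in dB, or \code{Inf}.
#' @export
psnr <- function(x, y, R) {
  if (!identical(dim(x), dim(y))) stop("images must share a shape")
  if (R <= 0) stop("R must be positive")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

#' Mean spectral angle mapper
#'
#' Per-pixel angle between the reference and test spectral vectors,
#' \code{arccos} of their normalised inner product (clamped to [-1, 1]),
#' averaged over all pixels. Scale-invariant per pixel. Zero test spectra
#' contribute the maximum angle of 90 degrees and are counted in the
#' \code{"zeroTestSpectra"} attribute.
#'
#' @param reference,test \linkS4class{HSCube}s of identical shape; the
#'   reference must contain no all-zero spectrum.
#' @param degrees report degrees (default) or radians.
#' @return Mean spectral angle.
#' @export
samMean <- function(reference, test, degrees = TRUE) {
  stopifnot(is(reference, "HSCube"), is(test, "HSCube"))
  if (!identical(dim(reference@data), dim(test@data)))
    stop("cubes must share a shape")
  d <- dim(reference@data)
  X <- matrix(reference@data, d[1] * d[2], d[3])
  Y <- matrix(test@data, d[1] * d[2], d[3])
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  if (any(nx == 0)) stop("reference cube contains all-zero spectra")
  zero <- ny == 0
  cosA <- rowSums(X * Y) / (nx * pmax(ny, .Machine$double.xmin))
  cosA <- pmin(pmax(cosA, -1), 1)
  ang <- acos(cosA)
  ang[zero] <- pi / 2
  out <- mean(ang)
  if (degrees) out <- out * 180 / pi
  attr(out, "zeroTestSpectra") <- sum(zero)
  out
}

#' Quality score: PSNR over SAM
#'
#' @param psnrDb PSNR in dB.
#' @param samDeg mean spectral angle in degrees, > 0.
#' @return \code{psnrDb / samDeg}.
#' @export
score1 <- function(psnrDb, samDeg) {
  if (samDeg <= 0) stop("samDeg must be positive")
  psnrDb / samDeg
}

#' Runtime-corrected quality score
#'
#' \code{score1 / (cfCpu * cfVolume * runtimeS)}; the correction factors
#' default to 1 and only apply to runtimes measured on foreign platforms
#' (faster CPU, smaller data volume).
#'
#' @param score1Val value of [score1()].
#' @param runtimeS runtime in seconds, > 0.
#' @param cfCpu,cfVolume positive correction factors.
#' @return Corrected score.
#' @export
score2 <- function(score1Val, runtimeS, cfCpu = 1, cfVolume = 1) {
  if (runtimeS <= 0 || cfCpu <= 0 || cfVolume <= 0)
    stop("runtime and correction factors must be positive")
  score1Val / (cfCpu * cfVolume * runtimeS)
}

#' Evaluate a super-resolved cube against the reference and baseline
#'
#' Computes per-band SSIM and PSNR for the super-resolved and baseline
#' cubes against the reference, plus the mean spectral angle for both. The
#' summary reports the mean relative SSIM gain in percent,
#' \code{mean((ssim_sr - ssim_bi) / ssim_bi) * 100}, and the mean PSNR gain
#' in dB; bands with infinite PSNR are excluded from the PSNR mean and
#' counted. Per band, the SSIM dynamic range L and the PSNR peak R both
#' default to the reference band's max - min.
#'
#' @param reference,sr,baseline \linkS4class{HSCube}s of identical shape and
#'   wavelengths.
#' @param params an \code{SSIMParams} bundle; its \code{dynamicRangeL} is
#'   overridden per band unless \code{fixedL} is TRUE.
#' @param fixedL use \code{params$dynamicRangeL} for every band instead of
#'   the per-band reference range.
#' @return A list of class \code{MetricsReport} with elements
#'   \code{perBand} (data.frame: band, wavelength, ssimSr, ssimBi, psnrSr,
#'   psnrBi) and \code{summary} (meanSsimGainPct, meanPsnrGainDb, samSrDeg,
#'   samBiDeg, infinitePsnrBands).
#' @export
evaluateCubes <- function(reference, sr, baseline, params = ssimParams(),
                          fixedL = FALSE) {
  stopifnot(is(reference, "HSCube"), is(sr, "HSCube"), is(baseline, "HSCube"))
  if (!identical(dim(reference@data), dim(sr@data)) ||
      !identical(dim(reference@data), dim(baseline@data)))
    stop("the three cubes must share a shape")
  B <- dim(reference@data)[3]
  perBand <- data.frame(band = seq_len(B) - 1L,
                        wavelength = reference@wavelengths,
                        ssimSr = NA_real_, ssimBi = NA_real_,
                        psnrSr = NA_real_, psnrBi = NA_real_)
  for (b in seq_len(B)) {
    ref <- selectBand(reference, b - 1L)
    sb <- selectBand(sr, b - 1L)
    bb <- selectBand(baseline, b - 1L)
    rng <- diff(range(ref))
    L <- if (fixedL) params$dynamicRangeL else max(rng, .Machine$double.eps)
    p <- ssimParams(params$k1, params$k2, L, params$window)
    perBand$ssimSr[b] <- ssim(ref, sb, p)
    perBand$ssimBi[b] <- ssim(ref, bb, p)
    perBand$psnrSr[b] <- psnr(ref, sb, L)
    perBand$psnrBi[b] <- psnr(ref, bb, L)
  }
  finite <- is.finite(perBand$psnrSr) & is.finite(perBand$psnrBi)
  summary <- list(
    meanSsimGainPct = mean((perBand$ssimSr - perBand$ssimBi) /
                           perBand$ssimBi) * 100,
    meanPsnrGainDb = if (any(finite))
      mean(perBand$psnrSr[finite] - perBand$psnrBi[finite]) else NA_real_,
    samSrDeg = as.numeric(samMean(reference, sr)),
    samBiDeg = as.numeric(samMean(reference, baseline)),
    infinitePsnrBands = sum(!finite)
  )
  structure(list(perBand = perBand, summary = summary),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport: %d bands | SSIM gain %.2f%% | PSNR gain %.3f dB | SAM %.3f vs %.3f deg\n",
    nrow(x$perBand), x$summary$meanSsimGainPct, x$summary$meanPsnrGainDb,
    x$summary$samSrDeg, x$summary$samBiDeg))
  invisible(x)
}
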