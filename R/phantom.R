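# Synthetic hyperspectral phantom: a stand-in for calibrated histology
# captures. Smooth elliptical regions with distinct spectral signatures ride
# on a shared broadband texture; bands are correlated so that one principal
# component dominates, and additive Gaussian sensor noise is applied.

#' Phantom specification
#'
#' Validated parameter bundle for [makePhantom()]. Defaults emulate a small
#' calibrated histology field of view: a 128 x 128 pixel window, 16 bands,
#' six tissue-like elliptical regions, reflectance-scale intensities around
#' 0.2-1.5, band correlation 0.9 (so the first principal component carries
#' most of the variance, as is typical of stained tissue), and additive
#' Gaussian noise of sd 0.01 (about 1% of the signal scale).
#'
#' @param height,width spatial size in HR pixels.
#' @param nBands number of spectral bands.
#' @param nBlobs number of elliptical regions.
#' @param noiseSigma additive Gaussian noise sd.
#' @param bandCorrelation in [0, 1]; fraction of each band's structured
#'   variance carried by the band-shared component. At 1 every band is a
#'   scalar multiple of the shared image plus noise.
#' @param seed integer RNG seed; the phantom is bit-reproducible given it.
#' @return A named list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(height = 128L, width = 128L, nBands = 16L,
                        nBlobs = 6L, noiseSigma = 0.01,
                        bandCorrelation = 0.9, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               nBands = as.integer(nBands), nBlobs = as.integer(nBlobs),
               noiseSigma = as.numeric(noiseSigma),
               bandCorrelation = as.numeric(bandCorrelation),
               seed = as.integer(seed))
  with(spec, {
    if (height < 1 || width < 1 || nBands < 1) stop("counts must be positive")
    if (nBlobs < 0) stop("nBlobs must be >= 0")
    if (noiseSigma < 0) stop("noiseSigma must be >= 0")
    if (bandCorrelation < 0 || bandCorrelation > 1)
      stop("bandCorrelation must lie in [0, 1]")
  })
  class(spec) <- "PhantomSpec"
  spec
}

# Smooth random field: white noise convolved with a truncated Gaussian along
# rows then columns (dense banded weighting matrices; sizes here are small).
.smoothField <- function(h, w, sigma) {
  k <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-d^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  f <- k(h) %*% matrix(stats::rnorm(h * w), h, w) %*% t(k(w))
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic hyperspectral phantom
#'
#' Deterministic given \code{spec$seed}. Band b is built as
#' \code{c_b * (1 + 0.25 * (sqrt(rho) * S + sqrt(1 - rho) * Z_b)
#' + 0.4 * sqrt(1 - rho) * sum_k B_k * (s_k(b) - mean(s_k)))} plus Gaussian
#' noise, clipped at 0, where S is a shared field (broadband texture plus
#' elliptical blobs), Z_b are independent per-band smooth fields, c_b a
#' smooth positive continuum, B_k the blob masks and s_k their smooth
#' spectral signatures. The texture guarantees non-zero image gradient in
#' every 16 x 16 tile so block matching is well-posed; the spectral
#' modulation vanishes as \code{rho} approaches 1, in which case bands are
#' scalar multiples of each other up to noise.
#'
#' @param spec a \code{PhantomSpec} from [phantomSpec()].
#' @return An \linkS4class{HSCube} with a synthetic 400-1000 nm wavelength
#'   axis.
#' @export
makePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  h <- spec$height; w <- spec$width; B <- spec$nBands
  rho <- spec$bandCorrelation
  set.seed(spec$seed)
  texture <- .smoothField(h, w, sigma = 6)
  blobs <- vector("list", spec$nBlobs)
  blobSum <- matrix(0, h, w)
  if (spec$nBlobs > 0) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (k in seq_len(spec$nBlobs)) {
      cy <- stats::runif(1, 0.15 * h, 0.85 * h)
      cx <- stats::runif(1, 0.15 * w, 0.85 * w)
      ry <- stats::runif(1, 0.08, 0.20) * h
      rx <- stats::runif(1, 0.08, 0.20) * w
      th <- stats::runif(1, 0, pi)
      u <- (rows - cy) * cos(th) + (cols - cx) * sin(th)
      v <- -(rows - cy) * sin(th) + (cols - cx) * cos(th)
      q <- (u / ry)^2 + (v / rx)^2
      blobs[[k]] <- exp(-q / 2)
      blobSum <- blobSum + blobs[[k]]
    }
  }
  shared <- texture + 1.5 * blobSum
  shared <- (shared - mean(shared)) / stats::sd(shared)
  # smooth positive continuum and smooth per-blob spectral signatures
  bIdx <- seq_len(B)
  continuum <- 0.8 + 0.2 * sin(2 * pi * bIdx / B + stats::runif(1, 0, 2 * pi))
  signatures <- lapply(seq_len(spec$nBlobs), function(k) {
    ctr <- stats::runif(1, 1, B)
    wid <- stats::runif(1, B / 6, B / 2)
    s <- exp(-((bIdx - ctr) / wid)^2)
    s - mean(s)
  })
  modAmp <- 0.4 * sqrt(1 - rho)
  cube <- array(0, c(h, w, B))
  for (b in seq_len(B)) {
    zb <- .smoothField(h, w, sigma = 6)
    img <- 1 + 0.25 * (sqrt(rho) * shared + sqrt(1 - rho) * zb)
    if (spec$nBlobs > 0 && modAmp > 0)
      for (k in seq_len(spec$nBlobs))
        img <- img + modAmp * blobs[[k]] * signatures[[k]][b]
    cube[, , b] <- continuum[b] * img
  }
  if (spec$noiseSigma > 0)
    cube <- cube + array(stats::rnorm(length(cube), sd = spec$noiseSigma),
                         dim(cube))
  cube <- pmax(cube, 0)
  wl <- seq(400, 1000, length.out = B)
  HSCube(cube, wavelengths = wl,
         meta = c(list(phantom = TRUE), unclass(spec)))
}
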