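# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain, slow enumerations so they stay independent of the package's
# vectorised implementations.

randomCube <- function(h = 8, w = 8, b = 5, seed = 42, integers = FALSE) {
  set.seed(seed)
  vals <- if (integers) sample.int(1000, h * w * b, replace = TRUE)
          else round(runif(h * w * b, 0, 100) * 4) / 4   # float32-exact
  HSCube(array(vals, c(h, w, b)),
         wavelengths = seq(400, 900, length.out = b))
}

texturedImage <- function(h = 48, w = 48, seed = 7) {
  set.seed(seed)
  k <- function(n, sigma = 3) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-d^2 / (2 * sigma^2)); K / rowSums(K)
  }
  f <- k(h) %*% matrix(rnorm(h * w), h, w) %*% t(k(w))
  (f - min(f)) / (max(f) - min(f))
}

# exhaustive integer block search with the documented tie-break
# (smallest SAD, then smallest Euclidean norm, then row-major dy, dx order)
naiveFsbm <- function(block, origin, target, range) {
  bh <- nrow(block); bw <- ncol(block)
  best <- NULL
  for (dy in -range:range) {
    for (dx in -range:range) {
      r0 <- origin[1] + dy; c0 <- origin[2] + dx
      if (r0 < 0 || c0 < 0 || r0 + bh > nrow(target) ||
          c0 + bw > ncol(target)) next
      s <- 0
      for (i in 1:bh) for (j in 1:bw)
        s <- s + abs(block[i, j] - target[r0 + i, c0 + j])
      cand <- c(dy = dy, dx = dx, sad = s)
      if (is.null(best) || s < best["sad"] ||
          (s == best["sad"] &&
           dy^2 + dx^2 < best["dy"]^2 + best["dx"]^2))
        best <- cand
    }
  }
  best
}

# independent two-pass corner-anchored bilinear upscaling (rows of samples
# interpolated along columns first, then along rows, with edge replication)
separableBilinearOracle <- function(image, ef) {
  h <- nrow(image); w <- ncol(image)
  H <- h * ef; W <- w * ef
  sampleRows <- (seq_len(h) - 1) * ef + 1
  sampleCols <- (seq_len(w) - 1) * ef + 1
  interp1 <- function(xs, ys, xout) {
    if (length(xs) == 1) return(rep(ys, length(xout)))
    approx(xs, ys, xout = xout, method = "linear", rule = 2)$y
  }
  tmp <- matrix(NA_real_, H, w)
  for (j in seq_len(w))
    tmp[, j] <- interp1(sampleRows, image[, j], seq_len(H))
  out <- matrix(NA_real_, H, W)
  for (i in seq_len(H))
    out[i, ] <- interp1(sampleCols, tmp[i, ], seq_len(W))
  out
}

# straightforward second implementation of global-statistics SSIM
globalSsimOracle <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  mx <- mean(x); my <- mean(y)
  n <- length(x)
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# direct double-loop Gaussian-window local SSIM (valid region)
localSsimOracle <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1,
                            win = 11, sigma = 1.5) {
  g1 <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  Wg <- outer(g1, g1)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1)) {
    for (j in seq_len(ncol(x) - win + 1)) {
      px <- x[i:(i + win - 1), j:(j + win - 1)]
      py <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(Wg * px); my <- sum(Wg * py)
      vx <- sum(Wg * px^2) - mx^2
      vy <- sum(Wg * py^2) - my^2
      cxy <- sum(Wg * px * py) - mx * my
      vals <- c(vals, (2 * mx * my + C1) * (2 * cxy + C2) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

motionMatrix <- function(motions) {
  t(vapply(motions, function(m) c(m@dyQ, m@dxQ), integer(2)))
}
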