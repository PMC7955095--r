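# Independent brute-force pixel-loop reference implementations used to
# validate the vectorized/library-backed pipeline stages bit-exactly on
# small images, plus small fixture builders.

oracleMeanFilter <- function(img, r = 1L) {
  n <- nrow(img); p <- ncol(img)
  out <- matrix(0L, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1L), n)
      jj <- min(max(j + dj, 1L), p)
      acc <- acc + img[ii, jj]
    }
    out[i, j] <- as.integer(round(acc / (2 * r + 1)^2))
  }
  out
}

oracleStretch <- function(img, satPct = 0.4) {
  v <- as.vector(img)
  n <- length(v)
  k <- floor(n * satPct / 200)
  s <- sort(v)
  lo <- s[k + 1]; hi <- s[n - k]
  if (hi <= lo) return(img)
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(v)) {
    val <- round((as.numeric(v[i]) - lo) * 65535 / (hi - lo))
    out[i] <- as.integer(min(max(val, 0), 65535))
  }
  out
}

# grayscale opening (erode then dilate) with a disc, min/max over the
# in-bounds neighborhood only, then top-hat.
oracleTopHat <- function(img, r) {
  offs <- which(outer((-r:r)^2, (-r:r)^2, "+") <= r^2, arr.ind = TRUE) - r - 1L
  n <- nrow(img); p <- ncol(img)
  mor <- function(m, f) {
    out <- matrix(0, n, p)
    for (i in seq_len(n)) for (j in seq_len(p)) {
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= p
      out[i, j] <- f(m[cbind(ii[ok], jj[ok])])
    }
    out
  }
  opened <- mor(mor(img, min), max)
  out <- pmax(round(img - opened), 0)
  storage.mode(out) <- "integer"
  out
}

# triangle threshold by explicit point-to-line geometry over candidate bins
oracleTriangle <- function(img) {
  h <- tabulate(as.integer(img) %/% 256L + 1L, 256L)
  nz <- which(h > 0L)
  first <- nz[1] - 1L; last <- nz[length(nz)] - 1L
  peak <- which.max(h) - 1L
  flipped <- (peak - first) > (last - peak)
  if (flipped) {
    h <- rev(h); peak <- 255L - peak; tail <- 255L - first
  } else tail <- last
  hp <- h[peak + 1]
  if (tail <= peak + 1L) {
    thr <- peak
  } else {
    L <- sqrt((tail - peak)^2 + hp^2)
    best <- -1; thr <- peak
    for (i in (peak + 1L):(tail - 1L)) {
      d <- abs((tail - peak) * (hp - h[i + 1]) - (peak - i) * (0 - hp)) / L
      if (d > best) { best <- d; thr <- i }
    }
  }
  if (flipped) thr <- 255L - thr
  as.integer(thr)
}

# random 16-bit test image with structure (blobs on noise) for oracle tests
randomImage16 <- function(n = 64L, seed = 1L) {
  set.seed(seed)
  base <- matrix(rpois(n * n, 800), n, n)
  for (k in 1:4) {
    cy <- runif(1, 8, n - 8); cx <- runif(1, 8, n - 8)
    r <- runif(1, 3, 6)
    ys <- pmax(1, floor(cy - r)):pmin(n, ceiling(cy + r))
    xs <- pmax(1, floor(cx - r)):pmin(n, ceiling(cx + r))
    for (i in ys) for (j in xs)
      if ((i - cy)^2 + (j - cx)^2 <= r^2)
        base[i, j] <- base[i, j] + round(runif(1, 2e4, 5e4))
  }
  out <- pmin(base, 65535L)
  storage.mode(out) <- "integer"
  out
}

# sinusoidal grating: parallel stripes at a given orientation (deg, CCW
# from x-axis; stripes run along that direction)
gratingImage <- function(n = 96L, angleDeg = 0, period = 8) {
  th <- (angleDeg + 90) * pi / 180   # wave vector perpendicular to stripes
  x <- outer(seq_len(n), seq_len(n), function(i, j)
    32767 + 32767 * cos(2 * pi * ((j * cos(th) - i * sin(th)) / period)))
  round(x)
}

randomMask <- function(n = 64L, p = 0.3) {
  matrix(runif(n * n) < p, n, n)
}
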