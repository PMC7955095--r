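# Low-level raster primitives shared by the MPM and coherency pipelines.
# These are deliberately simple, loop-free formulations whose output is
# bit-reproducible against a naive pixel-loop reference (the unit tests
# hold them to that).

# Replicate-pad a matrix by r pixels on every side.
.padReplicate <- function(m, r) {
  if (r == 0L) return(m)
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * r) - r, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * r) - r, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Symmetric (mirror, edge included) padding, used for Gaussian filtering.
.padSymmetric <- function(m, r) {
  if (r == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  ri <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, p), 1:p, pmax(p - seq_len(r) + 1L, 1L))
  m[ri, ci, drop = FALSE]
}

#' Mean filter with edge replication
#'
#' Replaces each pixel by the rounded mean of its (2 radius + 1)^2 square
#' neighborhood; pixels beyond the border take the nearest edge value.
#' Radius 1 (the default used for SHG/CARS smoothing) is a 3 x 3
#' neighborhood.
#'
#' @param image integer matrix (16-bit intensities).
#' @param radiusPx neighborhood radius in pixels (>= 0).
#' @return integer matrix of the same size.
#' @export
meanFilter <- function(image, radiusPx = 1L) {
  stopifnot(is.matrix(image), radiusPx >= 0)
  r <- as.integer(radiusPx)
  if (r == 0L) return(image)
  pad <- .padReplicate(image, r)
  n <- nrow(image); p <- ncol(image)
  acc <- matrix(0, n, p)
  for (di in 0:(2L * r)) for (dj in 0:(2L * r))
    acc <- acc + pad[di + seq_len(n), dj + seq_len(p)]
  out <- round(acc / (2L * r + 1L)^2)
  storage.mode(out) <- "integer"
  out
}

#' Linear min-max contrast stretch with saturated tails
#'
#' Linearly maps intensities to the full 16-bit range so that
#' \code{saturationPct} percent of pixels are clipped, split equally
#' between the dark and bright tails: with n pixels,
#' k = floor(n * saturationPct / 200) pixels saturate at each end, and the
#' (k+1)-th smallest / largest values map to 0 / 65535. A constant image is
#' returned unchanged (the stretch is undefined, and defined here as the
#' identity).
#'
#' @param image integer matrix.
#' @param saturationPct total percentage of clipped pixels (default 0.4).
#' @return integer matrix in \[0, 65535\].
#' @export
contrastStretch <- function(image, saturationPct = 0.4) {
  stopifnot(is.matrix(image), saturationPct >= 0, saturationPct < 100)
  v <- as.vector(image)
  n <- length(v)
  k <- floor(n * saturationPct / 200)
  s <- sort(v)
  lo <- s[k + 1L]
  hi <- s[n - k]
  if (hi <= lo) return(image)
  out <- round((as.numeric(image) - lo) * 65535 / (hi - lo))
  out <- pmin(pmax(out, 0), 65535)
  dim(out) <- dim(image)
  storage.mode(out) <- "integer"
  out
}

# Flat disc structuring element: x^2 + y^2 <= r^2.
.discBrush <- function(radiusPx) {
  r <- as.integer(radiusPx)
  d <- 2L * r + 1L
  xy <- seq_len(d) - r - 1L
  k <- outer(xy^2, xy^2, "+") <= r^2
  storage.mode(k) <- "numeric"
  k
}

#' Top-hat background subtraction
#'
#' Subtracts the grayscale morphological opening with a flat disc of the
#' given radius (the deterministic rolling-ball equivalent for a flat
#' structuring element) from the image, clipping at zero. Removes any
#' background structure wider than the disc while retaining objects
#' smaller than it.
#'
#' @param image integer matrix.
#' @param radiusPx disc radius in pixels; must be smaller than both image
#'   dimensions.
#' @return integer matrix (>= 0).
#' @export
subtractBackground <- function(image, radiusPx = 30L) {
  stopifnot(is.matrix(image), radiusPx >= 1)
  if (2L * radiusPx + 1L > min(dim(image)))
    stop("background radius must be smaller than the image")
  kern <- .discBrush(radiusPx)
  # EBImage grayscale morphology operates on [0, 1] intensities; min/max
  # selection commutes with the scaling, and the final round() absorbs the
  # one-ulp float error of the scale round trip
  opened <- EBImage::opening(image / 65535, kern) * 65535
  out <- as.numeric(image) - as.numeric(opened)
  out <- pmax(round(out), 0)
  dim(out) <- dim(image)
  storage.mode(out) <- "integer"
  out
}

#' Triangle-method automatic threshold (Zack)
#'
#' Computes a 256-bin histogram of the 16-bit range (bin = intensity
#' \code{\%/\%} 256), draws the line from the histogram peak to the
#' farthest nonzero bin (the longer tail), and returns the bin with the
#' maximum perpendicular distance below that line. Objects are assumed
#' bright: the mask convention is "bin strictly greater than the returned
#' threshold bin". Applied to the histogram as-is; dark-object images must
#' be inverted by the caller.
#'
#' @param image integer matrix with at least two distinct bin values.
#' @return integer threshold bin in \[0, 255\].
#' @seealso [binarizeCARS()]
#' @export
triangleThreshold <- function(image) {
  stopifnot(is.matrix(image))
  bins <- as.integer(as.vector(image)) %/% 256L
  h <- tabulate(bins + 1L, nbins = 256L)
  nz <- which(h > 0L)
  if (length(nz) < 2L)
    stop("triangle threshold undefined for a constant image")
  first <- nz[1L] - 1L; last <- nz[length(nz)] - 1L
  peak <- which.max(h) - 1L
  flipped <- (peak - first) > (last - peak)
  if (flipped) {
    h <- rev(h)
    peak <- 255L - peak
    tail <- 255L - first
  } else {
    tail <- last
  }
  # line through (peak, h[peak+1]) and (tail, 0); perpendicular distance of
  # (i, h[i+1]) is |dy*(i - peak) - dx*(h[i+1] - hp)| / len with dx, dy the
  # line direction. Search strictly between peak and tail.
  hp <- h[peak + 1L]
  if (tail <= peak + 1L) {
    thr <- peak
  } else {
    i <- (peak + 1L):(tail - 1L)
    d <- abs((0 - hp) * (i - peak) - (tail - peak) * (h[i + 1L] - hp))
    thr <- i[which.max(d)]
  }
  if (flipped) thr <- 255L - thr
  as.integer(thr)
}

# 8-connected component labeling via igraph.
.label8 <- function(mask) {
  stopifnot(is.logical(mask))
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  id <- matrix(0L, n, p)
  id[fg] <- seq_along(fg)
  rows <- (fg - 1L) %% n + 1L
  cols <- (fg - 1L) %/% n + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- rows + off[1L]; cc <- cols + off[2L]
    ok <- rr >= 1L & rr <= n & cc <= p
    if (!any(ok)) next
    nb <- id[cbind(rr[ok], cc[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(id[fg[ok]][hit], nb[hit]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Separable convolution along rows/cols with symmetric padding.
# kRow is applied along the row index (vertical), kCol along columns.
.convSep <- function(m, kRow, kCol) {
  r <- (length(kRow) - 1L) %/% 2L
  c <- (length(kCol) - 1L) %/% 2L
  pad <- .padSymmetric(m, max(r, c))
  extra <- max(r, c)
  n <- nrow(m); p <- ncol(m)
  # vertical pass
  tmp <- matrix(0, n, ncol(pad))
  for (k in seq_along(kRow))
    tmp <- tmp + kRow[k] * pad[(extra - r) + k - 1L + seq_len(n), ]
  out <- matrix(0, n, p)
  for (k in seq_along(kCol))
    out <- out + kCol[k] * tmp[, (extra - c) + k - 1L + seq_len(p)]
  out
}

.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

.gaussDerivKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  -(x / sigma^2) * g
}
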