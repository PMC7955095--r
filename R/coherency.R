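# Structure-tensor coherency: orientation order of the collagen mesh.
#
# The image gradient is taken with Gaussian derivative kernels; the outer
# products Jxx = <Ix Ix>, Jxy = <Ix Iy>, Jyy = <Iy Iy> are smoothed by a
# Gaussian window (or averaged over a whole subregion), and the coherency
# C = (l1 - l2) / (l1 + l2) of the averaged tensor contrasts its
# eigenvalues: C = 1 for perfectly parallel fibers, C = 0 for isotropic
# texture. Leaflet images are split into left and right halves because
# fibers run circumferentially to the annulus, so the preferred direction
# differs between the halves.

#' Structure tensor field of an image
#'
#' Gradients are computed with Gaussian derivative kernels (sigmaGrad),
#' using symmetric (reflective) border padding; the tensor components are
#' then smoothed with a Gaussian window (sigmaWindow; 0 skips the window,
#' leaving per-pixel outer products, appropriate when a whole-region
#' average follows). Angles follow the mathematical convention: x to the
#' right, y upward, counter-clockwise positive.
#'
#' @param image numeric matrix.
#' @param sigmaGrad gradient scale in px (> 0).
#' @param sigmaWindow window scale in px (>= 0; 0 = none).
#' @return list of matrices \code{Jxx}, \code{Jxy}, \code{Jyy}; the tensor
#'   is symmetric positive semidefinite at every pixel when
#'   \code{sigmaWindow = 0}, and remains so after Gaussian windowing.
#' @export
structureTensor <- function(image, sigmaGrad = 1, sigmaWindow = 0) {
  stopifnot(is.matrix(image), sigmaGrad > 0, sigmaWindow >= 0)
  m <- as.numeric(image)
  dim(m) <- dim(image)
  if (diff(range(m)) == 0) {
    z <- matrix(0, nrow(m), ncol(m))
    return(list(Jxx = z, Jxy = z, Jyy = z))
  }
  g <- .gaussKernel(sigmaGrad)
  dg <- .gaussDerivKernel(sigmaGrad)
  # row index grows downward; flip the sign of the vertical derivative so
  # that y points up and angles are CCW-positive from the x-axis
  Ix <- .convSep(m, g, dg)
  Iy <- -.convSep(m, dg, g)
  Jxx <- Ix * Ix; Jxy <- Ix * Iy; Jyy <- Iy * Iy
  if (sigmaWindow > 0) {
    wk <- .gaussKernel(sigmaWindow)
    Jxx <- .convSep(Jxx, wk, wk)
    Jxy <- .convSep(Jxy, wk, wk)
    Jyy <- .convSep(Jyy, wk, wk)
  }
  list(Jxx = Jxx, Jxy = Jxy, Jyy = Jyy)
}

#' Coherency and dominant orientation of a subregion
#'
#' Averages the structure-tensor components over the subregion mask
#' (energy-weighted single tensor -- bright, strongly oriented pixels
#' dominate, which stabilizes low-signal areas) and computes
#' C = (l1 - l2)/(l1 + l2) from its eigenvalues l1 >= l2 >= 0, with C = 0
#' by convention when l1 + l2 = 0 (e.g. a constant image). The dominant
#' angle is the fiber orientation (eigenvector of the smaller eigenvalue,
#' i.e. perpendicular to the mean gradient), in degrees within
#' \[-90, 90), counter-clockwise from the x-axis.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the subregion (default: whole image).
#' @param sigmaGrad gradient scale (px).
#' @param sigmaWindow tensor window scale (px); default 0 = average over
#'   the whole subregion only.
#' @param subregion label carried into the result (e.g. \code{"3.1"}).
#' @return a \linkS4class{CoherencyResult}.
#' @examples
#' img <- matrix(rep(c(0, 65535), each = 4, times = 8), 32, 32)  # stripes
#' coherencyAnalysis(img)@coherency
#' @export
coherencyAnalysis <- function(image, mask = NULL, sigmaGrad = 1,
                              sigmaWindow = 0, subregion = NA_character_) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))
  if (!any(mask)) stop("empty subregion mask")
  J <- structureTensor(image, sigmaGrad, sigmaWindow)
  jxx <- mean(J$Jxx[mask]); jxy <- mean(J$Jxy[mask]); jyy <- mean(J$Jyy[mask])
  trace <- jxx + jyy
  if (trace <= 0) {
    coh <- 0
    ang <- 0
  } else {
    diff <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
    coh <- diff / trace
    # gradient (major eigenvector) angle; fiber orientation is +90 deg
    gradAng <- 0.5 * atan2(2 * jxy, jxx - jyy)
    ang <- (gradAng * 180 / pi + 90)
    ang <- ((ang + 90) %% 180) - 90
  }
  new("CoherencyResult", subregion = as.character(subregion),
      coherency = min(max(coh, 0), 1), dominantAngleDeg = ang)
}

#' Split an image vertically into left/right half masks
#'
#' The split is at floor(width / 2) columns; for odd widths the middle
#' column goes to the left half. Left and right partition the image.
#'
#' @param image matrix (only the dimensions are used).
#' @return list of two logical matrices, \code{left} and \code{right}.
#' @export
splitHalves <- function(image) {
  stopifnot(is.matrix(image), ncol(image) >= 2L)
  w <- ncol(image)
  nLeft <- w - floor(w / 2)   # odd middle column assigned to left
  left <- matrix(FALSE, nrow(image), w)
  left[, seq_len(nLeft)] <- TRUE
  list(left = left, right = !left)
}

#' Coherency of the left and right halves of a leaflet-region image
#'
#' Applies [coherencyAnalysis()] to the two halves produced by
#' [splitHalves()], labeling subregions \code{"<region>.1"} (left) and
#' \code{"<region>.2"} (right).
#'
#' @param image numeric matrix (typically the middle slice of the SHG
#'   stack for the region).
#' @param region region number (1 tip, 2 middle, 3 base).
#' @param sigmaGrad,sigmaWindow see [coherencyAnalysis()].
#' @return list of two \linkS4class{CoherencyResult} objects.
#' @export
regionCoherency <- function(image, region, sigmaGrad = 1, sigmaWindow = 0) {
  halves <- splitHalves(image)
  list(
    coherencyAnalysis(image, halves$left, sigmaGrad, sigmaWindow,
                      subregion = paste0(region, ".1")),
    coherencyAnalysis(image, halves$right, sigmaGrad, sigmaWindow,
                      subregion = paste0(region, ".2")))
}
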