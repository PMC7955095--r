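# Picrosirius-red collagen quantification on RGB sections: color
# deconvolution (Beer-Lambert optical-density unmixing with a stain-vector
# matrix) followed by a manually specified optical-density threshold, plus
# section morphometry reusing the OCT measurement operators.

#' Default stain matrix for picrosirius-red sections
#'
#' Ruifrok-Johnston-style published vectors: a fast-red-type vector for
#' the picrosirius red stain, hematoxylin as counterstain, and the
#' normalized cross product as residual. Override per slide set when
#' calibration data exist; the original staining vectors of any given
#' scanner/stain lot are not universal.
#'
#' @return a \linkS4class{StainMatrix}.
#' @export
defaultStainMatrix <- function() {
  stainMatrix(psr_red = c(0.2140, 0.8511, 0.4779),
              counter = c(0.6500, 0.7040, 0.2860))
}

#' Construct a StainMatrix
#'
#' Vectors are normalized to unit length; the residual defaults to the
#' normalized cross product of the two stains (the direction neither
#' stain absorbs).
#'
#' @param psr_red optical-density RGB vector of the red collagen stain.
#' @param counter optical-density RGB vector of the counterstain.
#' @param residual optional third vector.
#' @return a \linkS4class{StainMatrix}.
#' @export
stainMatrix <- function(psr_red, counter, residual = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("zero stain vector")
    v / n
  }
  a <- unit(psr_red); b <- unit(counter)
  if (is.null(residual)) {
    r <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    if (sqrt(sum(r^2)) < 1e-8)
      stop("stain vectors are collinear")
    residual <- r
  }
  od <- rbind(psr_red = a, counter = b, residual = unit(residual))
  colnames(od) <- c("R", "G", "B")
  new("StainMatrix", od = od)
}

#' Color deconvolution of an RGB section scan
#'
#' Converts each 8-bit channel to optical density,
#' OD = -log10((I + 1) / 256), and inverts the stain matrix to obtain
#' per-stain concentration (OD-equivalent) rasters, clipped at zero.
#'
#' @param rgb h x w x 3 array of 8-bit values in \[0, 255\], or of
#'   normalized intensities in \[0, 1\] (as returned by TIFF readers),
#'   which are rescaled to 8 bits first.
#' @param stains a \linkS4class{StainMatrix}.
#' @return named list of numeric matrices \code{psr_red}, \code{counter},
#'   \code{residual}.
#' @examples
#' px <- array(255L, dim = c(2, 2, 3))        # pure white: no absorbance
#' range(colorDeconvolve(px, defaultStainMatrix())$psr_red)
#' @export
colorDeconvolve <- function(rgb, stains = defaultStainMatrix()) {
  stopifnot(is(stains, "StainMatrix"))
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("rgb must be an h x w x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("rgb values must lie in [0, 255] (8-bit)")
  if (max(rgb) <= 1 && !all(rgb == as.integer(rgb)))
    rgb <- round(rgb * 255)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  od <- -log10((matrix(as.numeric(rgb), h * w, 3L) + 1) / 256)
  M <- stains@od
  conc <- od %*% solve(M)          # solves conc %*% M = od
  conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], h, w))
  names(out) <- rownames(M)
  out
}

#' Picrosirius-red-positive area fraction
#'
#' Percentage of leaflet pixels whose red-stain concentration exceeds the
#' manually defined optical-density threshold. The threshold is a required
#' configuration value: it emulates the manual step reproducibly, and a QC
#' overlay can be written with [psrOverlay()].
#'
#' @param psrOd red-stain concentration matrix from [colorDeconvolve()].
#' @param leafletMask \linkS4class{BinaryMask} (or logical matrix) of the
#'   leaflet.
#' @param thresholdOd optical-density threshold (> strictly).
#' @return percentage in \[0, 100\].
#' @export
psrFraction <- function(psrOd, leafletMask, thresholdOd) {
  stopifnot(is.matrix(psrOd), is.numeric(thresholdOd))
  m <- if (is(leafletMask, "BinaryMask")) leafletMask@mask else leafletMask
  stopifnot(is.logical(m), identical(dim(m), dim(psrOd)))
  if (!any(m)) stop("empty leaflet mask")
  100 * sum(psrOd[m] > thresholdOd) / sum(m)
}

#' Write a QC overlay of the thresholded picrosirius-positive area
#'
#' @param rgb original h x w x 3 array.
#' @param psrOd red-stain concentration matrix.
#' @param thresholdOd threshold used.
#' @param path output TIFF path; positive pixels are marked in green.
#' @return \code{path}, invisibly.
#' @export
psrOverlay <- function(rgb, psrOd, thresholdOd, path) {
  pos <- psrOd > thresholdOd
  out <- rgb / 255
  g <- out[, , 2]
  g[pos] <- 1
  out[, , 2] <- g
  tiff::writeTIFF(out, path, bits.per.sample = 8L)
  invisible(path)
}

#' Morphometry of a histological section mask
#'
#' Reuses the OCT measurement operators (area = pixel count x pitch^2;
#' thickness = projected-bin chords per region) on a 2-D section mask,
#' with \code{source = "HISTOLOGY"}. Identical masks therefore give
#' identical numbers in both modalities.
#'
#' @param mask a \linkS4class{BinaryMask} of the section leaflet.
#' @param tipPoint,basePoint pixel coordinates of tip and base.
#' @param mode thickness aggregation, see [measureThickness()].
#' @return a \linkS4class{MorphometryResult}.
#' @export
sectionMorphometry <- function(mask, tipPoint, basePoint,
                               mode = c("mean", "max")) {
  leafletMorphometry(mask, tipPoint, basePoint, source = "HISTOLOGY",
                     mode = match.arg(mode))
}
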