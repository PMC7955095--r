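# SHG collagen quantification with cholesterol-crystal correction.
#
# Per slice: the SHG image is smoothed (mean filter, radius 1), linearly
# stretched (0.4 % saturated pixels) and binarized at a fixed count
# threshold (20000). Cholesterol crystals are SHG-active too, so their
# contribution is removed using the CARS channel: the CARS image is
# smoothed, stretched, background-subtracted (top-hat, disc radius 30) and
# binarized with the triangle method; the pixel-wise product of the two
# binary images isolates structures active in BOTH channels (the
# crystals), whose area fraction is subtracted from the SHG area fraction.
# Stack results are averaged per leaflet region.

#' Preprocess an SHG image (smooth, then stretch)
#'
#' Mean filter of the given radius followed by a linear min-max contrast
#' stretch with saturated tails. A constant image passes through
#' unchanged.
#'
#' @param image 16-bit integer matrix.
#' @param radiusPx mean-filter radius (default 1).
#' @param saturationPct stretch saturation percentage (default 0.4).
#' @return 16-bit integer matrix.
#' @export
preprocessSHG <- function(image, radiusPx = 1L, saturationPct = 0.4) {
  contrastStretch(meanFilter(image, radiusPx), saturationPct)
}

#' Binarize a preprocessed SHG image at a fixed intensity threshold
#'
#' The mask is TRUE where intensity is strictly above the threshold
#' ("above a threshold" read literally; pixels exactly at 20000 are
#' background).
#'
#' @param image preprocessed SHG matrix.
#' @param threshold intensity count threshold (default 20000).
#' @param pitchUm pixel pitch for the resulting mask.
#' @return a \linkS4class{BinaryMask}.
#' @export
binarizeSHG <- function(image, threshold = 20000, pitchUm = 0.28) {
  stopifnot(is.matrix(image), threshold >= 0)
  BinaryMask(image > threshold, pitchUm)
}

#' Preprocess a CARS image (smooth, stretch, subtract background)
#'
#' Mean filter, linear contrast stretch, then top-hat background
#' subtraction with a flat disc (radius 30 px by default), clipped at
#' zero.
#'
#' @param image 16-bit integer matrix.
#' @param radiusPx mean-filter radius (default 1).
#' @param saturationPct stretch saturation percentage (default 0.4).
#' @param backgroundRadiusPx background disc radius (default 30); must be
#'   smaller than the image.
#' @return 16-bit integer matrix (>= 0).
#' @export
preprocessCARS <- function(image, radiusPx = 1L, saturationPct = 0.4,
                           backgroundRadiusPx = 30L) {
  subtractBackground(contrastStretch(meanFilter(image, radiusPx),
                                     saturationPct),
                     backgroundRadiusPx)
}

#' Binarize a preprocessed CARS image with the triangle method
#'
#' Threshold chosen automatically on a 256-bin histogram of the 16-bit
#' range (see [triangleThreshold()]); TRUE strictly above the threshold
#' bin. A constant image has no definable threshold and raises an error;
#' pipeline callers map that to "no lipid detected".
#'
#' @param image preprocessed CARS matrix with at least two distinct
#'   256-level bins.
#' @param pitchUm pixel pitch for the resulting mask.
#' @return a \linkS4class{BinaryMask}.
#' @export
binarizeCARS <- function(image, pitchUm = 0.28) {
  thr <- triangleThreshold(image)
  bins <- matrix(as.integer(image) %/% 256L, nrow(image), ncol(image))
  BinaryMask(bins > thr, pitchUm)
}

#' Cholesterol-crystal-corrected SHG area fraction
#'
#' The crystal fraction is the area percentage of pixels active in both
#' the SHG and the CARS masks (their pixel-wise product); the corrected
#' collagen fraction is the SHG area percentage minus the crystal
#' percentage. By the identity area(A) - area(A and B) =
#' area(A and not B), the corrected fraction is never negative and the two
#' parts always sum exactly to the raw SHG fraction.
#'
#' @param shgMask,carsMask \linkS4class{BinaryMask} objects sharing
#'   geometry.
#' @param within optional leaflet \linkS4class{BinaryMask} used as area
#'   denominator; default whole image.
#' @return named numeric: \code{correctedPct}, \code{crystalPct},
#'   \code{rawShgPct}.
#' @export
crystalCorrectedFraction <- function(shgMask, carsMask, within = NULL) {
  stopifnot(is(shgMask, "BinaryMask"), is(carsMask, "BinaryMask"))
  .checkMaskGeom(shgMask, carsMask)
  raw <- areaPct(shgMask, within)
  crystal <- areaPct(shgMask & carsMask, within)
  c(correctedPct = raw - crystal, crystalPct = crystal, rawShgPct = raw)
}

#' Collagen area fraction of a full SHG/CARS stack
#'
#' Runs the per-slice chain (preprocess SHG, fixed-threshold binarize;
#' preprocess CARS, triangle binarize; crystal correction) on every slice
#' and averages the corrected percentages over the stack. A slice whose
#' preprocessed CARS image is constant contributes no crystal area (no
#' lipid detected).
#'
#' @param shg an SHG \linkS4class{ImageStack}.
#' @param cars the matching CARS \linkS4class{ImageStack}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param region leaflet region label (1 tip, 2 middle, 3 base) carried
#'   into the result.
#' @param within optional leaflet \linkS4class{BinaryMask} denominator.
#' @param qcDir optional directory; per-slice binary masks are written
#'   there as 8-bit TIFFs for visual inspection.
#' @return a \linkS4class{CollagenResult}.
#' @export
collagenStack <- function(shg, cars, config = loadConfig(),
                          region = NA_integer_, within = NULL, qcDir = NULL) {
  stopifnot(is(shg, "ImageStack"), is(cars, "ImageStack"),
            is(config, "PipelineConfig"))
  if (channel(shg) != "SHG" || channel(cars) != "CARS")
    stop("channel tags must be SHG and CARS (got ", channel(shg), " / ",
         channel(cars), ")")
  if (nSlices(shg) != nSlices(cars))
    stop("stacks differ in slice count")
  if (!identical(dim(pixels(shg)[[1L]]), dim(pixels(cars)[[1L]])))
    stop("stacks differ in slice geometry")
  ns <- nSlices(shg)
  corrected <- crystal <- numeric(ns)
  for (s in seq_len(ns)) {
    shgBin <- binarizeSHG(preprocessSHG(pixels(shg)[[s]],
                                        config@meanFilterRadiusPx,
                                        config@saturationPct),
                          config@shgThreshold, pitchUm(shg))
    carsPre <- preprocessCARS(pixels(cars)[[s]], config@meanFilterRadiusPx,
                              config@saturationPct,
                              config@backgroundRadiusPx)
    carsBin <- tryCatch(binarizeCARS(carsPre, pitchUm(cars)),
                        error = function(e)
                          BinaryMask(matrix(FALSE, nrow(carsPre),
                                            ncol(carsPre)), pitchUm(cars)))
    f <- crystalCorrectedFraction(shgBin, carsBin, within)
    corrected[s] <- f[["correctedPct"]]
    crystal[s] <- f[["crystalPct"]]
    if (!is.null(qcDir)) {
      dir.create(qcDir, showWarnings = FALSE, recursive = TRUE)
      writeMask(shgBin, file.path(qcDir, sprintf("shg_bin_%03d.tif", s)))
      writeMask(carsBin, file.path(qcDir, sprintf("cars_bin_%03d.tif", s)))
    }
  }
  new("CollagenResult", perSlicePct = corrected, perSliceCrystalPct = crystal,
      meanPct = mean(corrected), crystalCorrected = TRUE,
      region = as.integer(region))
}

#' Maximum intensity projection of a stack
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return integer matrix, per-pixel maximum across slices.
#' @export
maxIntensityProjection <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  out <- Reduce(pmax, pixels(stack))
  storage.mode(out) <- "integer"
  out
}

#' Qualitative lipid quantification from a CARS stack
#'
#' Computes the maximum intensity projection of the CARS stack (the total
#' lipid load through the leaflet thickness), segments it with the CARS
#' preprocessing + triangle threshold, and classifies each 8-connected
#' CARS-positive component as a cholesterol crystal if at least half of
#' its pixels are SHG-active (crystals generate SHG; droplets do not),
#' otherwise as a lipid droplet.
#'
#' Components smaller than \code{minComponentPx} are treated as noise
#' speckle and discarded (9 px is ~0.7 um^2 at the 0.28 um pixel pitch,
#' far below any resolvable droplet).
#'
#' @param cars a CARS \linkS4class{ImageStack}.
#' @param shg the aligned SHG \linkS4class{ImageStack}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param minComponentPx minimum component area kept (px).
#' @return a \linkS4class{LipidResult}.
#' @export
lipidSummary <- function(cars, shg, config = loadConfig(),
                         minComponentPx = 9L) {
  stopifnot(is(cars, "ImageStack"), is(shg, "ImageStack"))
  if (channel(cars) != "CARS" || channel(shg) != "SHG")
    stop("channel tags must be CARS and SHG")
  mip <- maxIntensityProjection(cars)
  shgMip <- maxIntensityProjection(shg)
  carsMask <- tryCatch({
    pre <- preprocessCARS(mip, config@meanFilterRadiusPx,
                          config@saturationPct, config@backgroundRadiusPx)
    maskPixels(binarizeCARS(pre))
  }, error = function(e) matrix(FALSE, nrow(mip), ncol(mip)))
  shgMask <- maskPixels(binarizeSHG(preprocessSHG(shgMip,
                                                  config@meanFilterRadiusPx,
                                                  config@saturationPct),
                                    config@shgThreshold))
  lab <- .label8(carsMask)
  nComp <- max(lab)
  dropletPx <- crystalPx <- 0L
  nDrop <- 0L
  if (nComp > 0L) for (k in seq_len(nComp)) {
    compIdx <- which(lab == k)
    if (length(compIdx) < minComponentPx) next
    shgFrac <- mean(shgMask[compIdx])
    if (shgFrac >= 0.5) {
      crystalPx <- crystalPx + length(compIdx)
    } else {
      dropletPx <- dropletPx + length(compIdx)
      nDrop <- nDrop + 1L
    }
  }
  npx <- length(mip)
  new("LipidResult", dropletCount = nDrop,
      dropletAreaPct = 100 * dropletPx / npx,
      crystalAreaPct = 100 * crystalPx / npx, mip = mip)
}
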