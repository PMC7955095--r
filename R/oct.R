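# OCT leaflet morphometry: isotropic resampling, optical-to-geometric
# axial correction, composite (slab-sum) cross-sections, and mask-based
# area and region-wise thickness.

# 1-D linear interpolation of an array along one axis at new coordinates
# (in units of the old pitch, 0-based voxel-center positions).
.interpAxis <- function(arr, axis, newPos) {
  d <- dim(arr)
  n <- d[axis]
  lo <- pmin(pmax(floor(newPos) + 1L, 1L), n)   # 1-based lower neighbor
  hi <- pmin(lo + 1L, n)
  wHi <- newPos - (lo - 1L)
  wHi <- pmin(pmax(wHi, 0), 1)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dim(a) <- c(n, prod(d[-axis]))
  out <- a[lo, , drop = FALSE] * (1 - wHi) + a[hi, , drop = FALSE] * wHi
  dim(out) <- c(length(newPos), d[setdiff(1:3, axis)])
  aperm(out, order(perm))
}

#' Rescale an OCT volume to isotropic voxels
#'
#' Trilinear resampling (sequential linear interpolation per axis, which
#' is exactly trilinear) to the target pitch on all three axes. The first
#' and last samples sit on the original voxel centers, so the physical
#' extent is preserved to within one voxel. A volume already at the target
#' pitch on some axis is passed through unchanged on that axis
#' (interpolation at the grid points).
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param targetPitchUm isotropic target pitch (default 2.255 um).
#' @return an \linkS4class{OCTVolume} with \code{isotropic = TRUE}.
#' @export
rescaleIsotropic <- function(vol, targetPitchUm = 2.255) {
  stopifnot(is(vol, "OCTVolume"), targetPitchUm > 0)
  arr <- vol@voxels
  for (ax in 1:3) {
    pitch <- vol@pitchUm[ax]
    n <- dim(arr)[ax]
    if (isTRUE(all.equal(pitch, targetPitchUm))) next
    extent <- (n - 1L) * pitch
    nNew <- floor(extent / targetPitchUm) + 1L
    newPos <- (seq_len(nNew) - 1L) * targetPitchUm / pitch
    arr <- .interpAxis(arr, ax, newPos)
  }
  OCTVolume(arr, pitchUm = rep(targetPitchUm, 3), axialAxis = vol@axialAxis,
            refractiveIndex = vol@refractiveIndex, isotropic = TRUE)
}

#' Convert optical to geometric axial length
#'
#' OCT measures optical path length; geometric depth is optical path
#' divided by the tissue refractive index. This divides the axial pitch by
#' n, leaving lateral axes untouched (the volume is then anisotropic again
#' if it was isotropic in optical units).
#'
#' @param vol an \linkS4class{OCTVolume} with axial pitch in optical um.
#' @param n refractive index (>= 1; default the volume's own, typically
#'   1.33 for water).
#' @return an \linkS4class{OCTVolume} with geometric axial pitch.
#' @export
opticalToGeometric <- function(vol, n = vol@refractiveIndex) {
  stopifnot(is(vol, "OCTVolume"))
  if (n < 1) stop("refractive index must be >= 1")
  pitch <- vol@pitchUm
  pitch[vol@axialAxis] <- pitch[vol@axialAxis] / n
  OCTVolume(vol@voxels, pitchUm = pitch, axialAxis = vol@axialAxis,
            refractiveIndex = n,
            isotropic = length(unique(signif(pitch, 12))) == 1L)
}

#' Composite cross-section by summing adjacent slices
#'
#' Sums the intensity values of \code{window} adjacent cross-sections
#' centered on \code{index} (floor((w-1)/2) before, the rest after) to
#' enhance tissue contrast and signal-to-noise; no averaging, so the
#' dynamic range widens by the window factor.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param index slice index along \code{alongAxis}.
#' @param window number of slices summed (default 10).
#' @param alongAxis axis perpendicular to the cross-section (default the
#'   second lateral axis, 2).
#' @return numeric matrix (the composite cross-section).
#' @export
compositeCrossSection <- function(vol, index, window = 10L, alongAxis = 2L) {
  stopifnot(is(vol, "OCTVolume"), window >= 1)
  n <- dim(vol@voxels)[alongAxis]
  lo <- index - floor((window - 1) / 2)
  hi <- lo + window - 1L
  if (lo < 1L || hi > n)
    stop(sprintf("window of %d slices around index %d exceeds volume (1..%d)",
                 window, index, n))
  idx <- lo:hi
  sl <- switch(alongAxis,
               vol@voxels[idx, , , drop = FALSE],
               vol@voxels[, idx, , drop = FALSE],
               vol@voxels[, , idx, drop = FALSE])
  apply(sl, setdiff(1:3, alongAxis), sum)
}

#' Physical area of a mask
#'
#' Pixel count times squared pitch. An empty mask yields 0 with a warning.
#'
#' @param mask a \linkS4class{BinaryMask} (isotropic pitch).
#' @param pitchUm optional pitch override (um/px).
#' @return area in um^2.
#' @examples
#' measureArea(BinaryMask(matrix(TRUE, 10, 10), pitchUm = 2.255))  # 508.5
#' @export
measureArea <- function(mask, pitchUm = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  p <- if (is.null(pitchUm)) mask@pitchUm else pitchUm
  n <- sum(mask@mask)
  if (n == 0L) {
    warning("empty mask: area is 0")
    return(0)
  }
  n * p^2
}

#' Assign tip/middle/base regions along the base-to-tip axis
#'
#' Projects mask pixels onto the base-to-tip axis and splits the projected
#' extent into three equal intervals; the tip-most third is region 1, the
#' base-most region 3.
#'
#' @param mask a \linkS4class{BinaryMask} of the leaflet.
#' @param tipPoint,basePoint numeric (column, row) or (x, z) pixel
#'   coordinates of the tip and base ends.
#' @return a \linkS4class{RegionGrid}.
#' @export
assignRegions <- function(mask, tipPoint, basePoint) {
  stopifnot(is(mask, "BinaryMask"), length(tipPoint) == 2L,
            length(basePoint) == 2L)
  v <- as.numeric(tipPoint) - as.numeric(basePoint)
  len <- sqrt(sum(v^2))
  if (len == 0) stop("tip and base points coincide")
  u <- v / len
  m <- mask@mask
  idx <- which(m, arr.ind = TRUE)   # (row, col)
  if (nrow(idx) == 0L) stop("empty mask")
  # coordinates as (x = first point coord, y = second); points are given
  # in the same (c1, c2) convention as the mask's (col-like, row-like)
  # axes used by the phantom truth: interpret point = (dim1, dim2) index.
  proj <- (idx[, 1L] - as.numeric(basePoint)[1L]) * u[1L] +
          (idx[, 2L] - as.numeric(basePoint)[2L]) * u[2L]
  rng <- range(proj)
  breaks <- rng[1L] + diff(rng) * c(1, 2) / 3
  lab <- ifelse(proj > breaks[2L], 1L, ifelse(proj > breaks[1L], 2L, 3L))
  labels <- matrix(0L, nrow(m), ncol(m))
  labels[idx] <- lab
  new("RegionGrid", labels = labels, axis = u)
}

#' Region-wise leaflet thickness from a mask
#'
#' Thickness is measured along rays perpendicular to the base-to-tip axis:
#' mask pixels are binned by their projection onto the axis (bins one
#' pitch wide), and the thickness at a bin is the mask pixel count in the
#' bin times pitch (total chord length, robust to mask roughness and
#' rotation). Per region the default aggregation is the mean over bins;
#' \code{mode = "max"} returns the maximum instead. A region with no mask
#' pixels yields \code{NaN}.
#'
#' @param mask a \linkS4class{BinaryMask} (isotropic pitch).
#' @param grid a \linkS4class{RegionGrid} from [assignRegions()].
#' @param pitchUm optional pitch override (um/px).
#' @param mode \code{"mean"} (default) or \code{"max"} chord aggregation.
#' @return named numeric, thickness per region in um
#'   (\code{region1..region3}).
#' @export
measureThickness <- function(mask, grid, pitchUm = NULL,
                             mode = c("mean", "max")) {
  stopifnot(is(mask, "BinaryMask"), is(grid, "RegionGrid"))
  mode <- match.arg(mode)
  if (!identical(dim(mask@mask), dim(grid@labels)))
    stop("grid does not cover the mask")
  p <- if (is.null(pitchUm)) mask@pitchUm else pitchUm
  idx <- which(mask@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  u <- grid@axis
  proj <- idx[, 1L] * u[1L] + idx[, 2L] * u[2L]
  bin <- floor(proj - min(proj))    # bins one pixel (= one pitch) wide
  lab <- grid@labels[idx]
  out <- stats::setNames(rep(NaN, 3L), paste0("region", 1:3))
  for (r in 1:3) {
    sel <- lab == r
    if (!any(sel)) next
    counts <- table(bin[sel])
    th <- as.numeric(counts) * p
    out[r] <- if (mode == "mean") mean(th) else max(th)
  }
  out
}

#' Full OCT morphometry of a leaflet cross-section mask
#'
#' @param mask a \linkS4class{BinaryMask} of the leaflet in a (composite)
#'   cross-section, isotropic geometric pitch.
#' @param tipPoint,basePoint pixel coordinates of tip and base (see
#'   [assignRegions()]).
#' @param source \code{"OCT"} or \code{"HISTOLOGY"}.
#' @param mode thickness aggregation, see [measureThickness()].
#' @return a \linkS4class{MorphometryResult}.
#' @export
leafletMorphometry <- function(mask, tipPoint, basePoint, source = "OCT",
                               mode = c("mean", "max")) {
  grid <- assignRegions(mask, tipPoint, basePoint)
  new("MorphometryResult", areaUm2 = measureArea(mask),
      thicknessUm = measureThickness(mask, grid, mode = match.arg(mode)),
      source = source)
}

#' Segment a composite OCT cross-section by Otsu's method
#'
#' Phantom and QC segmentation; real-data masks come from manual
#' segmentation and are supplied externally. Keeps the largest 8-connected
#' foreground component to suppress speckle islands.
#'
#' @param crossSection numeric matrix (e.g. from
#'   [compositeCrossSection()]).
#' @param pitchUm pixel pitch of the cross-section (um/px).
#' @return a \linkS4class{BinaryMask}.
#' @export
segmentCrossSection <- function(crossSection, pitchUm) {
  stopifnot(is.matrix(crossSection))
  x <- crossSection / max(crossSection)
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  fg <- x > thr
  lab <- .label8(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    fg <- lab == which.max(sizes)
  }
  BinaryMask(fg, pitchUm)
}
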