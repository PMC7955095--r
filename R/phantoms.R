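# Synthetic phantoms with exact ground truth. These stand in for the
# animals: every analysis stage in the package is validated against
# phantoms whose collagen fraction, crystal fraction, droplet count,
# orientation concentration and leaflet geometry are known by
# construction. Truth masks are always recorded BEFORE noise.

.subSeed <- function(seed, tag, i = 0L) {
  # double arithmetic: exact up to 2^53, avoids 32-bit overflow
  as.integer((as.numeric(seed) * 131 + as.numeric(tag) * 7919 +
                as.numeric(i) * 104729) %% 2147483629)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution on
# [-pi, pi). kappa = 0 degenerates to the uniform distribution.
.rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  ((mu + out + pi) %% (2 * pi)) - pi
}

# Anti-aliased oriented segment. Returns linear indices, coverage in
# [0, 1], and the exact (non-AA) mask indices (distance <= width/2).
.segmentFootprint <- function(h, w, cy, cx, angleDeg, lenPx, widthPx) {
  th <- angleDeg * pi / 180
  dx <- cos(th); dy <- -sin(th)   # row axis points down; CCW-positive angle
  hx <- dx * lenPx / 2; hy <- dy * lenPx / 2
  r <- widthPx / 2 + 1.5
  y0 <- max(1L, floor(cy - abs(hy) - r)); y1 <- min(h, ceiling(cy + abs(hy) + r))
  x0 <- max(1L, floor(cx - abs(hx) - r)); x1 <- min(w, ceiling(cx + abs(hx) + r))
  if (y0 > y1 || x0 > x1) return(NULL)
  ys <- y0:y1; xs <- x0:x1
  py <- rep(ys, times = length(xs)) - cy
  px <- rep(xs, each = length(ys)) - cx
  # distance from point to the segment [-(hx,hy), +(hx,hy)]
  L2 <- hx^2 + hy^2
  t <- if (L2 > 0) pmin(pmax((px * hx + py * hy) / L2, -1), 1) else 0
  ddx <- px - t * hx; ddy <- py - t * hy
  d <- sqrt(ddx^2 + ddy^2)
  cov <- pmin(pmax(widthPx / 2 + 0.5 - d, 0), 1)
  keep <- cov > 0
  if (!any(keep)) return(NULL)
  idx <- (rep(xs, each = length(ys)) - 1L) * h + rep(ys, times = length(xs))
  list(idx = idx[keep], cov = cov[keep], hard = d[keep] <= widthPx / 2)
}

.discFootprint <- function(h, w, cy, cx, radiusPx) {
  .segmentFootprint(h, w, cy, cx, 0, 0, 2 * radiusPx)
}

#' Generate a paired SHG/CARS multiphoton phantom with ground truth
#'
#' Renders straight anti-aliased collagen fiber segments with orientations
#' drawn from a von Mises distribution on the doubled-angle circle
#' (kappa = 0 gives an axially uniform mesh, large kappa parallel fibers)
#' into the SHG channel, lipid droplets into the CARS channel only, and
#' elongated cholesterol crystals at high intensity into BOTH channels --
#' the property the crystal correction exploits. Fibers are added until
#' the fiber-mask area fraction reaches \code{fiberDensity}. Gaussian read
#' noise and Poisson shot noise are applied after the truth masks are
#' recorded, then the images are quantized to 16 bits.
#'
#' Defaults mirror the acquisition geometry of the study the package
#' models: 500 x 500 px at 0.28 um/px (140 um field), 14 slices per stack.
#'
#' Droplets and crystals are volumetric structures: their lateral
#' positions are drawn once per phantom (with a minimum center separation
#' so that counts are well defined) and rendered into every slice, whereas
#' fibers are drawn per slice (each depth shows a different part of the
#' mesh). Fibers never cross droplet footprints -- lipid pools displace
#' the collagen mesh -- so droplets are SHG-dark, as in tissue.
#'
#' @param sizePx image size (rows, cols).
#' @param nSlices number of slices in the stack.
#' @param fiberDensity target collagen area fraction in \[0, 1\].
#' @param kappa von Mises concentration of fiber orientation (0 =
#'   isotropic).
#' @param meanAngleDeg preferred fiber orientation, degrees CCW from the
#'   x-axis.
#' @param fiberLengthPx,fiberWidthPx,fiberIntensity fiber rendering
#'   parameters (16-bit counts).
#' @param dropletCount,dropletRadiusPx,dropletIntensity CARS-only lipid
#'   droplets.
#' @param crystalCount,crystalLengthPx,crystalWidthPx,crystalIntensity
#'   cholesterol crystals, rendered into both channels; defaults are
#'   plate-like (45 x 9 px = 12.6 x 2.5 um at 0.28 um/px), the morphology
#'   of cholesterol crystal plates in tissue.
#' @param background baseline intensity (counts).
#' @param noiseGaussianSd additive Gaussian read-noise SD (counts).
#' @param noisePoissonScale photons per count for Poisson shot noise on
#'   signal; 0 disables it.
#' @param pitchUm pixel pitch (um/px).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return list with elements \code{shg}, \code{cars} (both
#'   \linkS4class{ImageStack}) and \code{truth}
#'   (\linkS4class{PhantomTruth}).
#' @examples
#' ph <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 1,
#'                          fiberDensity = 0.1, seed = 1)
#' ph$truth@collagenFractionPct
#' @export
generateMPMPhantom <- function(sizePx = c(500L, 500L), nSlices = 14L,
                               fiberDensity = 0.10, kappa = 2,
                               meanAngleDeg = 0, fiberLengthPx = 40,
                               fiberWidthPx = 3, fiberIntensity = 30000,
                               dropletCount = 0L, dropletRadiusPx = 6,
                               dropletIntensity = 40000, crystalCount = 0L,
                               crystalLengthPx = 45, crystalWidthPx = 9,
                               crystalIntensity = 50000, background = 1000,
                               noiseGaussianSd = 500, noisePoissonScale = 0.05,
                               pitchUm = 0.28, seed = 1L) {
  stopifnot(fiberDensity >= 0, fiberDensity <= 1, kappa >= 0,
            dropletCount >= 0, crystalCount >= 0)
  h <- as.integer(sizePx[1L]); w <- as.integer(sizePx[2L])
  npx <- h * w
  shg <- cars <- vector("list", nSlices)
  fiberMasks <- crystalMasks <- dropletMasks <- vector("list", nSlices)
  allAngles <- numeric()
  perFiber <- max(1, fiberLengthPx * fiberWidthPx)
  maxFibers <- ceiling(fiberDensity * npx / perFiber) * 50 + 100

  # volumetric structures: one set of lateral positions per phantom
  cry <- matrix(0, h, w)
  cryMask <- matrix(FALSE, h, w)
  centers <- NULL
  set.seed(.subSeed(seed, 2L))
  for (k in seq_len(crystalCount)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    ang <- stats::runif(1, -90, 90)
    fp <- .segmentFootprint(h, w, cy, cx, ang, crystalLengthPx, crystalWidthPx)
    if (is.null(fp)) next
    cry[fp$idx] <- pmax(cry[fp$idx], crystalIntensity * fp$cov)
    cryMask[fp$idx[fp$hard]] <- TRUE
    centers <- rbind(centers, c(cy, cx))
  }
  dro <- matrix(0, h, w)
  droMask <- matrix(FALSE, h, w)
  set.seed(.subSeed(seed, 3L))
  cryCenters <- centers
  droCenters <- NULL
  sepCry <- dropletRadiusPx + crystalLengthPx / 2 + 3
  sepDro <- 2 * dropletRadiusPx + 6
  placed <- 0L; tries <- 0L
  while (placed < dropletCount) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, dropletCount))
      stop("cannot place the requested droplets with minimum separation")
    m <- dropletRadiusPx + 2  # fully inside so counts survive projection
    cy <- stats::runif(1, m, h - m); cx <- stats::runif(1, m, w - m)
    if (!is.null(cryCenters) &&
        any(sqrt((cryCenters[, 1] - cy)^2 + (cryCenters[, 2] - cx)^2) < sepCry))
      next
    if (!is.null(droCenters) &&
        any(sqrt((droCenters[, 1] - cy)^2 + (droCenters[, 2] - cx)^2) < sepDro))
      next
    fp <- .discFootprint(h, w, cy, cx, dropletRadiusPx)
    if (is.null(fp)) next
    dro[fp$idx] <- pmax(dro[fp$idx], dropletIntensity * fp$cov)
    droMask[fp$idx[fp$hard]] <- TRUE
    droCenters <- rbind(droCenters, c(cy, cx))
    placed <- placed + 1L
  }

  for (s in seq_len(nSlices)) {
    fib <- matrix(0, h, w)
    fibMask <- matrix(FALSE, h, w)
    set.seed(.subSeed(seed, 1L, s))
    nf <- 0L
    while (fiberDensity > 0 && sum(fibMask) / npx < fiberDensity) {
      nf <- nf + 1L
      if (nf > maxFibers)
        stop("requested fiberDensity unreachable at this image size")
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      ang <- meanAngleDeg + (.rvonmises(1, 0, kappa) * 180 / pi) / 2
      allAngles <- c(allAngles, ang)
      fp <- .segmentFootprint(h, w, cy, cx, ang, fiberLengthPx, fiberWidthPx)
      if (is.null(fp)) next
      # droplets displace the collagen mesh, and crystal signal dominates
      # any collagen beneath a crystal plate, so the visible-collagen truth
      # excludes both footprints
      out <- droMask[fp$idx] | cryMask[fp$idx]
      fib[fp$idx] <- pmax(fib[fp$idx], fiberIntensity * fp$cov * !out)
      fibMask[fp$idx[fp$hard & !out]] <- TRUE
    }
    fiberMasks[[s]] <- fibMask
    crystalMasks[[s]] <- cryMask
    dropletMasks[[s]] <- droMask
    set.seed(.subSeed(seed, 4L, s))
    shg[[s]] <- .applyNoise(background + pmax(fib, cry), noiseGaussianSd,
                            noisePoissonScale)
    set.seed(.subSeed(seed, 5L, s))
    cars[[s]] <- .applyNoise(background + pmax(dro, cry), noiseGaussianSd,
                             noisePoissonScale)
  }
  truth <- new("PhantomTruth",
    collagenFractionPct = 100 * mean(vapply(fiberMasks, mean, numeric(1))),
    crystalFractionPct = 100 * mean(vapply(crystalMasks, mean, numeric(1))),
    dropletCount = as.integer(dropletCount), kappa = as.numeric(kappa),
    meanAngleDeg = as.numeric(meanAngleDeg), fiberMasks = fiberMasks,
    crystalMasks = crystalMasks, dropletMasks = dropletMasks,
    anglesDeg = allAngles)
  list(shg = ImageStack(shg, pitchUm = pitchUm, channel = "SHG"),
       cars = ImageStack(cars, pitchUm = pitchUm, channel = "CARS"),
       truth = truth)
}

.applyNoise <- function(signal, gaussSd, poissonScale) {
  x <- signal
  if (poissonScale > 0)
    x <- stats::rpois(length(x), lambda = pmax(x, 0) * poissonScale) /
      poissonScale
  if (gaussSd > 0)
    x <- x + stats::rnorm(length(signal), 0, gaussSd)
  out <- pmin(pmax(round(x), 0), 65535)
  dim(out) <- dim(signal)
  storage.mode(out) <- "integer"
  out
}

#' Generate an OCT phantom volume with a curved leaflet band
#'
#' Embeds a curved tissue band of known geometric thickness (piecewise
#' constant over the three leaflet regions, tip to base) in a speckled
#' volume. OCT measures optical path length, so the band's axial extent in
#' the stored volume is its geometric thickness multiplied by the
#' refractive index; a 100 um band at n = 1.33 spans 133 um of optical
#' axial path. Speckle is multiplicative Rayleigh (first-order OCT
#' statistics), mixed in with weight \code{speckleContrast}.
#'
#' @param volumePx voxel counts (x = base-to-tip lateral, y = lateral,
#'   z = axial/optical).
#' @param pitchUm per-axis pitch (um), z in optical path units.
#' @param thicknessUm geometric band thickness per region, tip first
#'   (region 1), length 3.
#' @param curvatureUm depth bow of the band center across the leaflet
#'   length (um, geometric).
#' @param tissueLevel,backgroundLevel mean intensities (16-bit counts).
#' @param speckleContrast multiplicative speckle mixing weight in
#'   \[0, 1\]; 0 gives a piecewise-constant volume.
#' @param refractiveIndex tissue refractive index used to convert
#'   geometric to optical axial length.
#' @param marginPx lateral margin of empty volume around the leaflet.
#' @param seed integer seed.
#' @return list with \code{volume} (\linkS4class{OCTVolume}, axial pitch
#'   in optical um) and \code{truth} (\linkS4class{PhantomTruth}; geometric
#'   thickness profile, geometric area of the central x-z cross-section,
#'   truth mask and tip/base voxel coordinates in
#'   \code{truth@leafletMask}).
#' @export
generateOCTPhantom <- function(volumePx = c(160L, 24L, 150L),
                               pitchUm = c(4, 4, 2),
                               thicknessUm = c(137, 90, 80),
                               curvatureUm = 40, tissueLevel = 30000,
                               backgroundLevel = 3000, speckleContrast = 0.6,
                               refractiveIndex = 1.33, marginPx = 8L,
                               seed = 1L) {
  stopifnot(length(volumePx) == 3L, length(pitchUm) == 3L,
            length(thicknessUm) == 3L, all(thicknessUm > 0),
            refractiveIndex >= 1, speckleContrast >= 0, speckleContrast <= 1)
  nx <- as.integer(volumePx[1L]); ny <- as.integer(volumePx[2L])
  nz <- as.integer(volumePx[3L])
  zExtentGeom <- nz * pitchUm[3L] / refractiveIndex
  if (max(thicknessUm) + curvatureUm > 0.9 * zExtentGeom)
    stop("band thicker than the volume allows")
  xIdx <- seq_len(nx)
  inLeaf <- xIdx > marginPx & xIdx <= nx - marginPx
  leafX <- which(inLeaf)
  nL <- length(leafX)
  # tip (region 1) at high x, base (region 3) at low x
  relPos <- (seq_len(nL) - 0.5) / nL            # 0 at base, 1 at tip
  region <- ifelse(relPos > 2 / 3, 1L, ifelse(relPos > 1 / 3, 2L, 3L))
  thickGeom <- numeric(nx)
  thickGeom[leafX] <- thicknessUm[region]
  zMid <- zExtentGeom / 2
  centerGeom <- rep(NA_real_, nx)
  centerGeom[leafX] <- zMid + curvatureUm * ((2 * relPos - 1)^2 - 0.5)
  # geometric depth of each voxel center along the optical axis
  zGeom <- ((seq_len(nz) - 0.5) * pitchUm[3L]) / refractiveIndex
  band <- matrix(FALSE, nx, nz)
  for (i in leafX)
    band[i, ] <- abs(zGeom - centerGeom[i]) <= thickGeom[i] / 2
  level <- array(backgroundLevel, dim = c(nx, ny, nz))
  bandArr <- aperm(array(band, dim = c(nx, nz, ny)), c(1, 3, 2))
  level[bandArr] <- tissueLevel
  set.seed(.subSeed(seed, 6L))
  if (speckleContrast > 0) {
    sigma <- sqrt(2 / pi)   # Rayleigh with unit mean
    r <- sigma * sqrt(-2 * log(stats::runif(length(level))))
    level <- level * ((1 - speckleContrast) + speckleContrast * r)
  }
  vox <- pmin(pmax(round(level), 0), 65535)
  dim(vox) <- c(nx, ny, nz)
  names(thicknessUm) <- paste0("region", 1:3)
  areaGeom <- sum(thickGeom[leafX]) * pitchUm[1L]
  tipPoint <- c(x = max(leafX), z = which.min(abs(zGeom - centerGeom[max(leafX)])))
  basePoint <- c(x = min(leafX), z = which.min(abs(zGeom - centerGeom[min(leafX)])))
  truth <- new("PhantomTruth",
    thicknessProfileUm = thicknessUm, areaUm2 = areaGeom,
    leafletMask = list(crossSection = band, tip = tipPoint, base = basePoint,
                       regionOfColumn = stats::setNames(region, leafX)))
  vol <- OCTVolume(vox, pitchUm = pitchUm, axialAxis = 3L,
                   refractiveIndex = refractiveIndex, isotropic = FALSE)
  list(volume = vol, truth = truth)
}

#' Generate a picrosirius-red histology phantom
#'
#' Renders collagen-positive blobs with the red-stain optical-density
#' vector and a uniform counterstain background via Beer-Lambert optical
#' density mixing, then converts to 8-bit RGB with the transmittance model
#' \code{I = 256 * 10^(-OD) - 1}. Blobs (random discs) are added until the
#' positive mask reaches the requested fraction of the leaflet mask.
#'
#' @param sizePx image size (rows, cols).
#' @param collagenFractionPct target positive-area percentage of the
#'   leaflet in \[0, 100\].
#' @param stains a \linkS4class{StainMatrix}; default
#'   [defaultStainMatrix()].
#' @param psrOd optical density of the red stain on positive pixels.
#' @param counterOd optical density of the counterstain everywhere.
#' @param blobRadiusPx mean blob radius (px).
#' @param leafletMask optional logical matrix restricting the leaflet;
#'   default whole image.
#' @param pitchUm pixel pitch (um/px).
#' @param seed integer seed.
#' @return list with \code{rgb} (h x w x 3 integer array in \[0, 255\]) and
#'   \code{truth} (\linkS4class{PhantomTruth}: exact positive fraction and
#'   mask).
#' @export
generateHistoPhantom <- function(sizePx = c(256L, 256L),
                                 collagenFractionPct = 50,
                                 stains = defaultStainMatrix(), psrOd = 1.0,
                                 counterOd = 0.3, blobRadiusPx = 5,
                                 leafletMask = NULL, pitchUm = 0.5,
                                 seed = 1L) {
  stopifnot(collagenFractionPct >= 0, collagenFractionPct <= 100,
            is(stains, "StainMatrix"))
  h <- as.integer(sizePx[1L]); w <- as.integer(sizePx[2L])
  if (is.null(leafletMask)) leafletMask <- matrix(TRUE, h, w)
  stopifnot(identical(dim(leafletMask), c(h, w)))
  nLeaf <- sum(leafletMask)
  target <- collagenFractionPct / 100
  pos <- matrix(FALSE, h, w)
  set.seed(.subSeed(seed, 7L))
  tries <- 0L
  while (sum(pos & leafletMask) / nLeaf < target) {
    tries <- tries + 1L
    if (tries > 50 * nLeaf / max(1, pi * blobRadiusPx^2))
      stop("requested collagen fraction unreachable")
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    r <- stats::runif(1, 0.6, 1.4) * blobRadiusPx
    fp <- .discFootprint(h, w, cy, cx, r)
    if (is.null(fp)) next
    pos[fp$idx[fp$hard]] <- TRUE
  }
  pos <- pos & leafletMask
  odPsr <- ifelse(pos, psrOd, 0)
  odCnt <- ifelse(leafletMask, counterOd, 0)
  M <- stains@od
  rgb <- array(0L, dim = c(h, w, 3L))
  for (c in 1:3) {
    od <- odPsr * M["psr_red", c] + odCnt * M["counter", c]
    ch <- pmin(pmax(round(256 * 10^(-od) - 1), 0), 255)
    rgb[, , c] <- as.integer(ch)
  }
  truth <- new("PhantomTruth",
    collagenFractionPct = 100 * sum(pos) / nLeaf,
    leafletMask = list(positive = pos, leaflet = leafletMask))
  list(rgb = rgb, truth = truth)
}
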