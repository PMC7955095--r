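#' @import methods
NULL

.CHANNELS <- c("SHG", "CARS", "TPEF")

#' ImageStack: a calibrated multiphoton image stack
#'
#' Ordered set of 2-D 16-bit intensity rasters sharing one in-plane pixel
#' pitch, tagged with the acquisition channel. Physical calibration travels
#' with the object: multiphoton stacks (0.28 um pixels) and OCT volumes
#' (2.255 um voxels) coexist in one analysis, so a global pitch would be
#' a bug factory.
#'
#' @slot pixels list of integer matrices (one per slice), values in
#'   \[0, 65535\], identical dimensions.
#' @slot pitchUm in-plane pixel pitch in micrometers (isotropic in-plane).
#' @slot zStepUm axial step in micrometers; scalar or one value per
#'   inter-slice gap; may be \code{NA} (the step is varied per specimen so
#'   each stack spans the full leaflet thickness).
#' @slot channel one of \code{"SHG"}, \code{"CARS"}, \code{"TPEF"}.
#'
#' @seealso [readStack()], [generateMPMPhantom()]
#' @export
setClass("ImageStack",
  representation(pixels = "list", pitchUm = "numeric", zStepUm = "numeric",
                 channel = "character"),
  prototype(pixels = list(), pitchUm = 0.28, zStepUm = NA_real_,
            channel = "SHG"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@pixels) == 0L)
    msg <- c(msg, "stack must contain at least one slice")
  if (!all(vapply(object@pixels, is.matrix, logical(1))))
    msg <- c(msg, "all slices must be matrices")
  if (length(object@pixels) > 0L) {
    d <- dim(object@pixels[[1L]])
    if (!all(vapply(object@pixels, function(m) identical(dim(m), d), logical(1))))
      msg <- c(msg, "all slices must share dimensions")
    rng <- range(vapply(object@pixels, function(m) range(m), numeric(2)))
    if (rng[1] < 0 || rng[2] > 65535)
      msg <- c(msg, "intensities must lie in [0, 65535]")
  }
  if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
      object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (!object@channel %in% .CHANNELS)
    msg <- c(msg, sprintf("channel must be one of %s",
                          paste(.CHANNELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param pixels a matrix or list of matrices with values in \[0, 65535\].
#' @param pitchUm in-plane pixel pitch (um/px).
#' @param zStepUm axial step (um); may be \code{NA}.
#' @param channel acquisition channel, \code{"SHG"}, \code{"CARS"} or
#'   \code{"TPEF"}.
#' @return an \linkS4class{ImageStack}.
#' @examples
#' s <- ImageStack(matrix(0L, 8, 8), pitchUm = 0.28, channel = "SHG")
#' nSlices(s)
#' @export
ImageStack <- function(pixels, pitchUm = 0.28, zStepUm = NA_real_,
                       channel = c("SHG", "CARS", "TPEF")) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  pixels <- lapply(pixels, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("ImageStack", pixels = pixels, pitchUm = as.numeric(pitchUm),
      zStepUm = as.numeric(zStepUm), channel = match.arg(channel))
}

#' OCTVolume: a calibrated 3-D OCT intensity raster
#'
#' OCT measures optical path length along the axial axis; the axial pitch
#' is therefore in optical micrometers until divided by the tissue
#' refractive index (see [opticalToGeometric()]).
#'
#' @slot voxels 3-D numeric array, axes (x, y, z).
#' @slot pitchUm per-axis voxel pitch in micrometers, length 3 (x, y, z).
#' @slot axialAxis which array axis is the optical (depth) axis; default 3.
#' @slot refractiveIndex assumed mean tissue refractive index (>= 1).
#' @slot isotropic TRUE once all three pitches are equal (after
#'   [rescaleIsotropic()]).
#' @export
setClass("OCTVolume",
  representation(voxels = "array", pitchUm = "numeric", axialAxis = "integer",
                 refractiveIndex = "numeric", isotropic = "logical"),
  prototype(pitchUm = c(2.255, 2.255, 2.255), axialAxis = 3L,
            refractiveIndex = 1.33, isotropic = FALSE))

setValidity("OCTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array")
  if (length(object@pitchUm) != 3L || any(!is.finite(object@pitchUm)) ||
      any(object@pitchUm <= 0))
    msg <- c(msg, "pitchUm must be three positive numbers (x, y, z)")
  if (!object@axialAxis %in% 1:3)
    msg <- c(msg, "axialAxis must be 1, 2 or 3")
  if (object@refractiveIndex < 1)
    msg <- c(msg, "refractiveIndex must be >= 1")
  if (isTRUE(object@isotropic) &&
      length(unique(signif(object@pitchUm, 12))) != 1L)
    msg <- c(msg, "isotropic volume must have equal pitches on all axes")
  if (length(msg)) msg else TRUE
})

#' Construct an OCTVolume
#'
#' @param voxels 3-D numeric array (x, y, z).
#' @param pitchUm per-axis pitch in um, length 3.
#' @param axialAxis array axis holding optical depth (default 3).
#' @param refractiveIndex assumed mean refractive index (default 1.33,
#'   water).
#' @param isotropic logical; TRUE if all pitches already equal.
#' @return an \linkS4class{OCTVolume}.
#' @export
OCTVolume <- function(voxels, pitchUm, axialAxis = 3L, refractiveIndex = 1.33,
                      isotropic = length(unique(pitchUm)) == 1L) {
  new("OCTVolume", voxels = voxels, pitchUm = as.numeric(pitchUm),
      axialAxis = as.integer(axialAxis),
      refractiveIndex = as.numeric(refractiveIndex),
      isotropic = isTRUE(isotropic))
}

#' BinaryMask: a boolean raster with physical calibration
#'
#' @slot mask logical matrix.
#' @slot pitchUm pixel pitch in micrometers.
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", pitchUm = "numeric"),
  prototype(pitchUm = 1))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (anyNA(object@mask))
    msg <- c(msg, "mask must not contain NA")
  if (length(object@pitchUm) != 1L || object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param mask logical (or 0/1) matrix.
#' @param pitchUm pixel pitch (um/px).
#' @return a \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(mask, pitchUm = 1) {
  if (!is.logical(mask)) {
    m <- mask > 0
    dim(m) <- dim(mask)
    mask <- m
  }
  new("BinaryMask", mask = mask, pitchUm = as.numeric(pitchUm))
}

#' PipelineConfig: all tunable constants of the quantification pipeline
#'
#' Houses the constants the quantification depends on: the fixed SHG
#' intensity threshold (20000 counts on the stretched 16-bit image), the
#' contrast-stretch saturation (0.4 % of pixels clipped, split between
#' tails), the smoothing mean-filter radius (1 px), the CARS background
#' subtraction radius (30 px), the isotropic OCT voxel target (2.255 um),
#' the assumed refractive index (1.33, water), the OCT slab-sum window
#' (10 cross-sections) and the significance level (0.05).
#'
#' @slot shgThreshold intensity count threshold for SHG binarization.
#' @slot saturationPct percent of pixels clipped by the contrast stretch.
#' @slot meanFilterRadiusPx radius of the smoothing mean filter (px).
#' @slot backgroundRadiusPx structuring-disc radius for CARS background
#'   subtraction (px).
#' @slot octTargetPitchUm isotropic OCT voxel target (um).
#' @slot refractiveIndex assumed mean tissue refractive index.
#' @slot compositeWindow number of adjacent OCT cross-sections summed.
#' @slot alpha significance level for group comparisons.
#' @slot seed integer seed for stochastic steps.
#' @export
setClass("PipelineConfig",
  representation(shgThreshold = "numeric", saturationPct = "numeric",
                 meanFilterRadiusPx = "numeric", backgroundRadiusPx = "numeric",
                 octTargetPitchUm = "numeric", refractiveIndex = "numeric",
                 compositeWindow = "numeric", alpha = "numeric",
                 seed = "numeric"),
  prototype(shgThreshold = 20000, saturationPct = 0.4, meanFilterRadiusPx = 1,
            backgroundRadiusPx = 30, octTargetPitchUm = 2.255,
            refractiveIndex = 1.33, compositeWindow = 10, alpha = 0.05,
            seed = 1))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@shgThreshold < 0) msg <- c(msg, "shgThreshold must be >= 0")
  if (object@saturationPct < 0 || object@saturationPct >= 100)
    msg <- c(msg, "saturationPct must lie in [0, 100)")
  if (object@meanFilterRadiusPx < 0)
    msg <- c(msg, "meanFilterRadiusPx must be >= 0")
  if (object@backgroundRadiusPx <= 0)
    msg <- c(msg, "backgroundRadiusPx must be > 0")
  if (object@octTargetPitchUm <= 0)
    msg <- c(msg, "octTargetPitchUm must be > 0")
  if (object@refractiveIndex < 1)
    msg <- c(msg, "refractiveIndex must be >= 1")
  if (object@compositeWindow < 1)
    msg <- c(msg, "compositeWindow must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: exact ground truth of a synthetic phantom
#'
#' Records everything the generator knows: per-slice masks of fibers,
#' crystals and droplets (computed before noise), the exact area fractions
#' they imply, the orientation parameters, and for OCT phantoms the
#' geometric thickness profile and leaflet area.
#'
#' @slot collagenFractionPct exact fiber-mask area fraction (%).
#' @slot crystalFractionPct exact crystal-mask area fraction (%).
#' @slot dropletCount number of lipid droplets rendered.
#' @slot kappa von Mises concentration of fiber orientation.
#' @slot meanAngleDeg preferred fiber orientation (degrees).
#' @slot fiberMasks,crystalMasks,dropletMasks per-slice logical matrices.
#' @slot anglesDeg rendered fiber segment angles (degrees, all slices).
#' @slot thicknessProfileUm geometric leaflet thickness per region (um),
#'   names "region1".."region3" (OCT / histology phantoms).
#' @slot areaUm2 geometric leaflet area (um^2).
#' @slot leafletMask list holding the leaflet/label masks where relevant.
#' @export
setClass("PhantomTruth",
  representation(collagenFractionPct = "numeric", crystalFractionPct = "numeric",
                 dropletCount = "integer", kappa = "numeric",
                 meanAngleDeg = "numeric", fiberMasks = "list",
                 crystalMasks = "list", dropletMasks = "list",
                 anglesDeg = "numeric", thicknessProfileUm = "numeric",
                 areaUm2 = "numeric", leafletMask = "list"),
  prototype(collagenFractionPct = NA_real_, crystalFractionPct = NA_real_,
            dropletCount = 0L, kappa = NA_real_, meanAngleDeg = NA_real_,
            fiberMasks = list(), crystalMasks = list(), dropletMasks = list(),
            anglesDeg = numeric(), thicknessProfileUm = numeric(),
            areaUm2 = NA_real_, leafletMask = list()))

#' RegionGrid: tip/middle/base labeling of a leaflet mask
#'
#' Region 1 is the free edge of the tip (nodulus), region 2 the middle,
#' region 3 the base (annulus/hinge). Labels partition the leaflet mask.
#'
#' @slot labels integer matrix; 0 outside the leaflet, 1..3 the regions.
#' @slot axis unit vector (column, row) pointing base -> tip.
#' @export
setClass("RegionGrid",
  representation(labels = "matrix", axis = "numeric"))

setValidity("RegionGrid", function(object) {
  msg <- character()
  if (!all(object@labels %in% 0:3))
    msg <- c(msg, "labels must take values 0, 1, 2 or 3")
  if (length(object@axis) != 2L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must be a 2-D unit vector")
  if (length(msg)) msg else TRUE
})

#' StainMatrix: optical-density stain vectors for color deconvolution
#'
#' Rows are unit optical-density vectors (R, G, B) of the stains:
#' \code{psr_red} (picrosirius red), \code{counter} (counterstain) and
#' \code{residual} (complement). Must be non-singular.
#'
#' @slot od 3x3 numeric matrix, rows = stains, columns = R, G, B; each row
#'   normalized to unit length.
#' @export
setClass("StainMatrix", representation(od = "matrix"))

setValidity("StainMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@od), c(3L, 3L)))
    msg <- c(msg, "od must be a 3x3 matrix")
  else {
    nrm <- sqrt(rowSums(object@od^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "stain vectors must be unit length")
    if (abs(det(object@od)) < 1e-8)
      msg <- c(msg, "stain vectors are collinear (singular matrix)")
  }
  if (length(msg)) msg else TRUE
})

#' CollagenResult: SHG collagen fraction for one leaflet region stack
#'
#' @slot perSlicePct crystal-corrected SHG-positive area fraction per
#'   slice (%).
#' @slot perSliceCrystalPct crystal (SHG- and CARS-active) area fraction
#'   per slice (%).
#' @slot meanPct arithmetic mean of \code{perSlicePct} over the stack.
#' @slot crystalCorrected whether the cholesterol-crystal correction was
#'   applied.
#' @slot region leaflet region (1 tip, 2 middle, 3 base); NA if unknown.
#' @export
setClass("CollagenResult",
  representation(perSlicePct = "numeric", perSliceCrystalPct = "numeric",
                 meanPct = "numeric", crystalCorrected = "logical",
                 region = "integer"),
  prototype(region = NA_integer_, crystalCorrected = TRUE))

setValidity("CollagenResult", function(object) {
  msg <- character()
  if (any(object@perSlicePct < 0 | object@perSlicePct > 100))
    msg <- c(msg, "per-slice percentages must lie in [0, 100]")
  if (length(object@perSlicePct) &&
      abs(object@meanPct - mean(object@perSlicePct)) > 1e-9)
    msg <- c(msg, "meanPct must equal the mean of perSlicePct")
  if (length(msg)) msg else TRUE
})

#' LipidResult: qualitative lipid quantification from a CARS stack
#'
#' @slot dropletCount number of lipid droplets (CARS-only connected
#'   components, 8-connectivity).
#' @slot dropletAreaPct droplet area fraction of the projection (%).
#' @slot crystalAreaPct cholesterol-crystal (SHG-active) area fraction (%).
#' @slot mip maximum intensity projection of the CARS stack.
#' @export
setClass("LipidResult",
  representation(dropletCount = "integer", dropletAreaPct = "numeric",
                 crystalAreaPct = "numeric", mip = "matrix"))

#' CoherencyResult: orientation order of collagen fibers in a subregion
#'
#' @slot subregion label such as \code{"3.1"} (region 3, left half).
#' @slot coherency structure-tensor coherency in \[0, 1\]: 1 for perfectly
#'   parallel fibers, 0 for isotropic texture.
#' @slot dominantAngleDeg dominant fiber orientation, degrees in
#'   \[-90, 90), counter-clockwise from the image x-axis.
#' @export
setClass("CoherencyResult",
  representation(subregion = "character", coherency = "numeric",
                 dominantAngleDeg = "numeric"),
  prototype(subregion = NA_character_))

setValidity("CoherencyResult", function(object) {
  if (object@coherency < -1e-12 || object@coherency > 1 + 1e-12)
    "coherency must lie in [0, 1]" else TRUE
})

#' MorphometryResult: leaflet area and region-wise thickness
#'
#' @slot areaUm2 leaflet area (um^2).
#' @slot thicknessUm named numeric, mean thickness per region (um);
#'   \code{NaN} for regions without mask pixels.
#' @slot source \code{"OCT"} or \code{"HISTOLOGY"}.
#' @export
setClass("MorphometryResult",
  representation(areaUm2 = "numeric", thicknessUm = "numeric",
                 source = "character"),
  prototype(source = "OCT"))

setValidity("MorphometryResult", function(object) {
  msg <- character()
  if (!object@source %in% c("OCT", "HISTOLOGY"))
    msg <- c(msg, "source must be OCT or HISTOLOGY")
  if (any(stats::na.omit(object@thicknessUm) < 0))
    msg <- c(msg, "thickness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroupComparison: one two-group test with normality-gated routing
#'
#' @slot metric name of the compared quantity.
#' @slot meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @slot normalityP per-group normality p-values (Kolmogorov-Smirnov,
#'   Lilliefors-corrected).
#' @slot test \code{"t_one_tailed"} or \code{"mann_whitney"}.
#' @slot direction the pre-specified one-tailed alternative
#'   (\code{"greater"}/\code{"less"}, group A relative to group B).
#' @slot pValue one-tailed p-value.
#' @slot alpha significance level.
#' @slot significant \code{pValue < alpha}.
#' @export
setClass("GroupComparison",
  representation(metric = "character", meanA = "numeric", sdA = "numeric",
                 nA = "integer", meanB = "numeric", sdB = "numeric",
                 nB = "integer", normalityP = "numeric", test = "character",
                 direction = "character", pValue = "numeric",
                 alpha = "numeric", significant = "logical"),
  prototype(metric = NA_character_, alpha = 0.05))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!object@test %in% c("t_one_tailed", "mann_whitney"))
    msg <- c(msg, "test must be t_one_tailed or mann_whitney")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
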