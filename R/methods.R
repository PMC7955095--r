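#' @describeIn nSlices slice count of a stack
#' @export
setMethod("nSlices", "ImageStack", function(x) length(x@pixels))

#' @describeIn pitchUm in-plane pitch of a stack
#' @export
setMethod("pitchUm", "ImageStack", function(x) x@pitchUm)

#' @describeIn pitchUm per-axis pitch of a volume
#' @export
setMethod("pitchUm", "OCTVolume", function(x) x@pitchUm)

#' @describeIn pitchUm pitch of a mask
#' @export
setMethod("pitchUm", "BinaryMask", function(x) x@pitchUm)

#' @describeIn pixels slice list of a stack
#' @export
setMethod("pixels", "ImageStack", function(x) x@pixels)

#' @describeIn channel channel tag of a stack
#' @export
setMethod("channel", "ImageStack", function(x) x@channel)

#' @describeIn voxels voxel array of a volume
#' @export
setMethod("voxels", "OCTVolume", function(x) x@voxels)

#' @describeIn maskPixels logical matrix of a mask
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@mask)

#' @describeIn areaPct area percent of a mask
#' @export
setMethod("areaPct", "BinaryMask", function(x, within = NULL) {
  if (is.null(within)) return(100 * sum(x@mask) / length(x@mask))
  stopifnot(is(within, "BinaryMask"))
  if (!identical(dim(x@mask), dim(within@mask)))
    stop("mask geometries differ")
  denom <- sum(within@mask)
  if (denom == 0L) stop("reference mask is empty")
  100 * sum(x@mask & within@mask) / denom
})

#' @describeIn areaUm2 physical area of a mask
#' @export
setMethod("areaUm2", "BinaryMask", function(x) sum(x@mask) * x@pitchUm^2)

#' @rdname BinaryMask-class
#' @param e1,e2 \linkS4class{BinaryMask} objects sharing geometry and pitch.
#' @export
setMethod("&", signature("BinaryMask", "BinaryMask"), function(e1, e2) {
  .checkMaskGeom(e1, e2)
  BinaryMask(e1@mask & e2@mask, e1@pitchUm)
})

#' @rdname BinaryMask-class
#' @export
setMethod("|", signature("BinaryMask", "BinaryMask"), function(e1, e2) {
  .checkMaskGeom(e1, e2)
  BinaryMask(e1@mask | e2@mask, e1@pitchUm)
})

#' @rdname BinaryMask-class
#' @param x a \linkS4class{BinaryMask}.
#' @export
setMethod("!", "BinaryMask", function(x) BinaryMask(!x@mask, x@pitchUm))

.checkMaskGeom <- function(a, b) {
  if (!identical(dim(a@mask), dim(b@mask)))
    stop("mask geometries differ")
  if (!isTRUE(all.equal(a@pitchUm, b@pitchUm)))
    stop("mask pitches differ")
  invisible(TRUE)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels[[1L]])
  cat(sprintf("ImageStack [%s]: %d slice(s) of %d x %d px, %.3g um/px (%.3g x %.3g um field)\n",
              object@channel, length(object@pixels), d[1], d[2],
              object@pitchUm, d[2] * object@pitchUm, d[1] * object@pitchUm))
})

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("OCTVolume: %d x %d x %d voxels, pitch (%.4g, %.4g, %.4g) um%s, n = %.3g\n",
              d[1], d[2], d[3], object@pitchUm[1], object@pitchUm[2],
              object@pitchUm[3],
              if (object@isotropic) " (isotropic)" else "",
              object@refractiveIndex))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %.4g um/px, %.2f%% positive (%.4g um^2)\n",
              nrow(object@mask), ncol(object@mask), object@pitchUm,
              100 * sum(object@mask) / length(object@mask),
              sum(object@mask) * object@pitchUm^2))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-20s %s\n", s, format(slot(object, s))))
})

setMethod("show", "CollagenResult", function(object) {
  cat(sprintf("CollagenResult (region %s): mean %.2f%% over %d slice(s)%s\n",
              ifelse(is.na(object@region), "?", object@region), object@meanPct,
              length(object@perSlicePct),
              if (object@crystalCorrected) ", crystal-corrected" else ""))
})

setMethod("show", "LipidResult", function(object) {
  cat(sprintf("LipidResult: %d droplet(s), droplet area %.2f%%, crystal area %.2f%%\n",
              object@dropletCount, object@dropletAreaPct,
              object@crystalAreaPct))
})

setMethod("show", "CoherencyResult", function(object) {
  cat(sprintf("CoherencyResult (subregion %s): C = %.3f, dominant angle %.1f deg\n",
              object@subregion, object@coherency, object@dominantAngleDeg))
})

setMethod("show", "MorphometryResult", function(object) {
  th <- paste(sprintf("%s = %.1f um", names(object@thicknessUm),
                      object@thicknessUm), collapse = ", ")
  cat(sprintf("MorphometryResult [%s]: area %.0f um^2; thickness %s\n",
              object@source, object@areaUm2, th))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]: %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d); %s, P = %.4g %s\n",
              object@metric, object@meanA, object@sdA, object@nA,
              object@meanB, object@sdB, object@nB, object@test,
              object@pValue, significanceStars(object@pValue)))
})
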