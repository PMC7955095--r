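#' Number of slices in a stack
#' @param x an \linkS4class{ImageStack}.
#' @return integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' Pixel/voxel pitch in micrometers
#' @param x a calibrated image object.
#' @return numeric pitch (scalar for 2-D objects, length 3 for volumes).
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))

#' Slice pixel data
#' @param x an \linkS4class{ImageStack}.
#' @return list of integer matrices.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Acquisition channel tag
#' @param x an \linkS4class{ImageStack}.
#' @return \code{"SHG"}, \code{"CARS"} or \code{"TPEF"}.
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' Voxel data of a volume
#' @param x an \linkS4class{OCTVolume}.
#' @return 3-D numeric array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Logical pixel mask
#' @param x a \linkS4class{BinaryMask}.
#' @return logical matrix.
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' Mask area as percent of the raster (or of a reference mask)
#'
#' @param x a \linkS4class{BinaryMask}.
#' @param within optional \linkS4class{BinaryMask} used as denominator
#'   (e.g. a leaflet mask); default is the whole raster.
#' @return percentage in \[0, 100\].
#' @export
setGeneric("areaPct", function(x, within = NULL) standardGeneric("areaPct"))

#' Mask area in square micrometers
#' @param x a \linkS4class{BinaryMask}.
#' @return area in um^2 (pixel count x pitch^2).
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))
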