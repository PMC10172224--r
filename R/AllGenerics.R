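#' @importFrom methods new validObject setClass setGeneric setMethod is slot
NULL

#' Pixel matrix of a 2-D image object
#'
#' @param x an object holding a 2-D image.
#' @return A numeric matrix in (row, column) = (y, x) orientation.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Physical pixel size in micrometres per pixel side
#'
#' @param x an image-bearing object.
#' @return A positive numeric scalar.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Voxel array of a channel stack
#'
#' @param x a \linkS4class{ChannelStack}.
#' @return A 3-D array indexed (z, y, x).
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Nominal bit depth of the acquisition
#'
#' @param x a \linkS4class{ChannelStack}.
#' @return An integer scalar (nominally 12).
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Channel name tag
#'
#' @param x a \linkS4class{ChannelStack}.
#' @return A character scalar.
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' Identifiers of the cells in a compartment map
#'
#' @param x a \linkS4class{CompartmentMap}.
#' @return An integer vector of positive cell labels.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Per-object table of a foci set
#'
#' @param x a \linkS4class{FociSet}.
#' @return A data.frame with one row per segmented object.
#' @export
setGeneric("fociTable", function(x) standardGeneric("fociTable"))

#' Pixel index lists of a foci set
#'
#' @param x a \linkS4class{FociSet}.
#' @return A list of integer vectors of linear pixel indices (column-major,
#'   matching the image the set was segmented from).
#' @export
setGeneric("fociPixels", function(x) standardGeneric("fociPixels"))

#' Local density index matrix of a density map
#'
#' @param x a \linkS4class{DensityMap}.
#' @return An integer matrix with values 0-8 on foreground pixels and NA on
#'   background.
#' @export
setGeneric("ldi", function(x) standardGeneric("ldi"))
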