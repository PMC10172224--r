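# S4 containers for the pipeline. Conventions used across the package:
#  - matrices are (row, column) = (y, x); pixel coordinates in outputs are
#    0-based (y, x)
#  - linear pixel indices are column-major R indices into the image matrix
#  - all object connectivity is 8-neighbor

#' One fluorescence channel as a z-stack with acquisition metadata
#'
#' Raw integer intensities of a single channel, ordered (z, y, x). Nominal
#' bit depth is 12 although values are stored in whatever container the TIFF
#' provided; values above \code{2^bitDepth - 1} are tolerated (frame
#' accumulation can exceed the nominal depth) but flagged with a warning at
#' construction, never clipped.
#'
#' @slot voxels 3-D numeric array (z, y, x) of non-negative intensities.
#' @slot bitDepth integer, nominal bit depth.
#' @slot pixelSize numeric, micrometres per pixel side (square pixels).
#' @slot channelName character tag, e.g. "DAPI" or "S9.6".
#' @export
setClass("ChannelStack",
  representation(voxels = "array", bitDepth = "integer",
                 pixelSize = "numeric", channelName = "character"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3-D array (z, y, x)")
    if (dim(v)[1L] < 1L) return("stack must contain at least one section")
    if (any(v < 0, na.rm = TRUE)) return("intensities must be non-negative")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a positive scalar (um)")
    if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
      return("bitDepth must be a positive integer")
    TRUE
  })

#' Construct a ChannelStack
#'
#' @param voxels 3-D array (z, y, x) of non-negative intensities.
#' @param bitDepth nominal bit depth (default 12).
#' @param pixelSize micrometres per pixel side (default 0.1).
#' @param channelName channel tag.
#' @return A \linkS4class{ChannelStack}.
#' @examples
#' cs <- ChannelStack(array(0:23, c(2, 3, 4)))
#' dim(voxels(cs))
#' @export
ChannelStack <- function(voxels, bitDepth = 12L, pixelSize = 0.1,
                         channelName = "") {
  obj <- new("ChannelStack", voxels = voxels, bitDepth = as.integer(bitDepth),
             pixelSize = pixelSize, channelName = channelName)
  vmax <- suppressWarnings(max(voxels))
  if (is.finite(vmax) && vmax > 2^obj@bitDepth - 1)
    warning("intensities exceed the nominal ", obj@bitDepth,
            "-bit range (max = ", vmax, "); values kept unclipped")
  obj
}

#' A single 2-D image with physical pixel size
#'
#' Houses projections and intermediate maps. Intensities may be integer
#' (raw, median maps) or real (fused/enhanced images).
#'
#' @slot pixels numeric matrix (y, x), non-negative.
#' @slot pixelSize micrometres per pixel side.
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(object@pixels < 0, na.rm = TRUE))
      return("pixel values must be non-negative")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a positive scalar (um)")
    TRUE
  })

#' Construct an Image2D
#'
#' @param pixels numeric matrix (y, x).
#' @param pixelSize micrometres per pixel side (default 0.1).
#' @return An \linkS4class{Image2D}.
#' @examples
#' img <- Image2D(matrix(0, 4, 4))
#' @export
Image2D <- function(pixels, pixelSize = 0.1) {
  new("Image2D", pixels = pixels, pixelSize = pixelSize)
}

#' Per-cell nucleus and cytoplasm compartments
#'
#' Labels partition the segmented cell foreground; the nucleus mask is a
#' subset of the labeled pixels, and each cell's cytoplasm is its label
#' minus its nucleus, so the two compartments are disjoint by construction.
#'
#' @slot cellLabels integer matrix, 0 = background, k > 0 = cell k.
#' @slot nucleusMask logical matrix of nuclear pixels.
#' @slot cellIds integer vector of the labels present.
#' @export
setClass("CompartmentMap",
  representation(cellLabels = "matrix", nucleusMask = "matrix",
                 cellIds = "integer"),
  validity = function(object) {
    if (!identical(dim(object@cellLabels), dim(object@nucleusMask)))
      return("cellLabels and nucleusMask must share dimensions")
    if (any(object@nucleusMask & object@cellLabels == 0L))
      return("every nucleus pixel must lie inside a labeled cell")
    ids <- setdiff(sort(unique(as.integer(object@cellLabels))), 0L)
    if (!identical(ids, sort(object@cellIds)))
      return("cellIds must list exactly the labels present")
    TRUE
  })

#' Discrete foci and clusters segmented from the marker channel
#'
#' One row of \code{fociTable(x)} per object: id, cell_id, compartment
#' ("nucleus"/"cytoplasm"), area (pixels), mean_intensity, total_intensity
#' (both measured on the original, un-preprocessed marker image),
#' centroid_y/centroid_x (0-based) and object_class ("focus",
#' "perinuclear_cluster" or "nucleolar_cluster"). Pixel memberships are in
#' \code{fociPixels(x)} as column-major linear indices.
#'
#' @slot objects data.frame as described above.
#' @slot pixels list of integer vectors, parallel to the rows of objects.
#' @slot dim integer(2), dimensions of the source image.
#' @export
setClass("FociSet",
  representation(objects = "data.frame", pixels = "list", dim = "integer"),
  validity = function(object) {
    df <- object@objects
    need <- c("id", "cell_id", "compartment", "area", "mean_intensity",
              "total_intensity", "centroid_y", "centroid_x", "object_class")
    if (!all(need %in% names(df)))
      return(paste("objects must contain columns:", paste(need, collapse = ", ")))
    if (nrow(df) != length(object@pixels))
      return("one pixel list per object row required")
    if (nrow(df) > 0L) {
      if (!all(df$area == lengths(object@pixels)))
        return("area must equal the number of member pixels")
      if (!all(df$compartment %in% c("nucleus", "cytoplasm")))
        return("compartment must be 'nucleus' or 'cytoplasm'")
      ok <- df$object_class %in% c("focus", "perinuclear_cluster",
                                   "nucleolar_cluster")
      if (!all(ok)) return("unknown object_class")
      if (any(df$object_class != "focus" & df$compartment != "nucleus"))
        return("clusters exist only in the nucleus")
      tol <- pmax(abs(df$total_intensity), 1) * 1e-8
      if (any(abs(df$mean_intensity * df$area - df$total_intensity) > tol))
        return("mean_intensity * area must equal total_intensity")
    }
    TRUE
  })

FociSet <- function(objects, pixels, dim) {
  new("FociSet", objects = objects, pixels = pixels, dim = as.integer(dim))
}

emptyFociSet <- function(dim) {
  FociSet(objects = data.frame(id = integer(), cell_id = integer(),
                               compartment = character(), area = integer(),
                               mean_intensity = numeric(),
                               total_intensity = numeric(),
                               centroid_y = numeric(), centroid_x = numeric(),
                               object_class = character(),
                               stringsAsFactors = FALSE),
          pixels = list(), dim = dim)
}

#' Density distribution map (DDM)
#'
#' Per-pixel local density indices of a binary mask: for every foreground
#' pixel, the number of foreground pixels among its 8 neighbors in the 3x3
#' window (0 = isolated, 8 = fully connected). Background pixels carry NA.
#'
#' @slot ldi integer matrix with values 0-8 on foreground, NA elsewhere.
#' @slot mask logical matrix, the source foreground.
#' @export
setClass("DensityMap",
  representation(ldi = "matrix", mask = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@ldi), dim(object@mask)))
      return("ldi and mask must share dimensions")
    fg <- object@ldi[object@mask]
    if (length(fg) && (any(is.na(fg)) || any(fg < 0L | fg > 8L)))
      return("LDI must be 0..8 on every foreground pixel")
    if (any(!is.na(object@ldi[!object@mask])))
      return("LDI must be NA on background pixels")
    TRUE
  })

## ---- accessors & show methods -------------------------------------------

#' @rdname pixels
#' @export
setMethod("pixels", "Image2D", function(x) x@pixels)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Image2D", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixelSize)

#' @rdname voxels
#' @export
setMethod("voxels", "ChannelStack", function(x) x@voxels)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "ChannelStack", function(x) x@bitDepth)

#' @rdname channelName
#' @export
setMethod("channelName", "ChannelStack", function(x) x@channelName)

#' @rdname cellIds
#' @export
setMethod("cellIds", "CompartmentMap", function(x) x@cellIds)

#' @rdname fociTable
#' @export
setMethod("fociTable", "FociSet", function(x) x@objects)

#' @rdname fociPixels
#' @export
setMethod("fociPixels", "FociSet", function(x) x@pixels)

#' @rdname ldi
#' @export
setMethod("ldi", "DensityMap", function(x) x@ldi)

#' Number of objects in a foci set
#' @param x a \linkS4class{FociSet}.
#' @export
setMethod("length", "FociSet", function(x) nrow(x@objects))

#' Nucleus mask of one cell
#'
#' @param map a \linkS4class{CompartmentMap}.
#' @param cell a cell id from \code{cellIds(map)}.
#' @return Logical matrix.
#' @export
nucleusOf <- function(map, cell) {
  stopifnot(is(map, "CompartmentMap"), cell %in% map@cellIds)
  map@nucleusMask & map@cellLabels == cell
}

#' Cytoplasm mask of one cell (cell pixels minus its nucleus)
#'
#' @inheritParams nucleusOf
#' @return Logical matrix.
#' @export
cytoplasmOf <- function(map, cell) {
  stopifnot(is(map, "CompartmentMap"), cell %in% map@cellIds)
  map@cellLabels == cell & !map@nucleusMask
}

#' Cell label image of a compartment map
#' @param map a \linkS4class{CompartmentMap}.
#' @return Integer matrix (0 = background).
#' @export
cellLabels <- function(map) {
  stopifnot(is(map, "CompartmentMap"))
  map@cellLabels
}

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ChannelStack '%s': %d section(s) of %d x %d px, %d-bit, %.3g um/px\n",
              object@channelName, d[1], d[2], d[3], object@bitDepth,
              object@pixelSize))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSize, min(object@pixels),
              max(object@pixels)))
})

setMethod("show", "CompartmentMap", function(object) {
  cat(sprintf("CompartmentMap: %d cell(s) over %d x %d px (%d nuclear px)\n",
              length(object@cellIds), nrow(object@cellLabels),
              ncol(object@cellLabels), sum(object@nucleusMask)))
})

setMethod("show", "FociSet", function(object) {
  tb <- table(factor(object@objects$object_class,
                     levels = c("focus", "perinuclear_cluster",
                                "nucleolar_cluster")))
  cat(sprintf("FociSet: %d object(s) [%d foci, %d perinuclear, %d nucleolar]\n",
              nrow(object@objects), tb[1], tb[2], tb[3]))
})

setMethod("show", "DensityMap", function(object) {
  n <- sum(object@mask)
  cat(sprintf("DensityMap: %d foreground px over %d x %d", n,
              nrow(object@mask), ncol(object@mask)))
  if (n > 0)
    cat(sprintf(", LDI range %d..%d", min(object@ldi, na.rm = TRUE),
                max(object@ldi, na.rm = TRUE)))
  cat("\n")
})
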