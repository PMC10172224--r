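# Nucleus / cell / foci segmentation following the quantitative-imaging
# procedure: adaptive nucleus masks from the counterstain, watershed cell
# separation seeded by nuclei, and local-median-map foci segmentation with
# geodesic splitting of overlapping blobs.

#' Segmentation parameter set
#'
#' @param median_window odd window (px) for the foci-stage local median map.
#'   Kept small so that resolution-limited (1-pixel) foci survive; default 3.
#' @param median_window_nuclei odd window (px) for the nuclear median map
#'   (mode "median_map"); default 5.
#' @param nuclear_mode counterstain preprocessing: "contrast_enhanced"
#'   (CLAHE; default) or "median_map" (for noisier, e.g. irradiated,
#'   material).
#' @param tophat_radius disc radius (px) of the white top-hat applied before
#'   the median map in cytoplasm foci segmentation; default 7 (larger than
#'   any focus, smaller than cytoplasmic shading scale).
#' @param cluster_area_threshold dimension criterion (px): nuclear objects
#'   strictly above it are clusters. A mandatory, logged analysis parameter
#'   to be matched to the data at hand; default 20.
#' @param fusion_rule channel fusion rule for whole-cell detection, "max"
#'   (default) or "sum".
#' @param min_nucleus_area smallest admissible nucleus component (px);
#'   default 50.
#' @return A validated list of class "SegmentationParams".
#' @export
segParams <- function(median_window = 3L, median_window_nuclei = 5L,
                      nuclear_mode = c("contrast_enhanced", "median_map"),
                      tophat_radius = 7L, cluster_area_threshold = 20L,
                      fusion_rule = c("max", "sum"), min_nucleus_area = 50L) {
  nuclear_mode <- match.arg(nuclear_mode)
  fusion_rule <- match.arg(fusion_rule)
  p <- list(median_window = as.integer(median_window),
            median_window_nuclei = as.integer(median_window_nuclei),
            nuclear_mode = nuclear_mode,
            tophat_radius = as.integer(tophat_radius),
            cluster_area_threshold = as.integer(cluster_area_threshold),
            fusion_rule = fusion_rule,
            min_nucleus_area = as.integer(min_nucleus_area))
  stopifnot(p$median_window %% 2L == 1L, p$median_window >= 3L,
            p$median_window_nuclei %% 2L == 1L,
            p$tophat_radius >= 1L, p$cluster_area_threshold > 1L,
            p$min_nucleus_area >= 1L)
  class(p) <- "SegmentationParams"
  p
}

.box3 <- function() matrix(1, 3, 3)  # 8-connected structuring element

#' Segment nuclei from the counterstain channel
#'
#' Preprocesses per \code{nuclear_mode} (local median map or CLAHE),
#' thresholds with Otsu's criterion, takes one conservative erosion step
#' (3x3, radius 1), fills holes and drops components below
#' \code{min_nucleus_area}.
#'
#' @param dapi counterstain \linkS4class{Image2D} or matrix.
#' @param params a \code{\link{segParams}} object.
#' @return Logical nucleus mask.
#' @export
segmentNuclei <- function(dapi, params = segParams()) {
  m <- .px(dapi)
  pre <- switch(params$nuclear_mode,
    median_map = .px(localMedianMap(m, params$median_window_nuclei)),
    contrast_enhanced = .px(enhanceLocalContrast(m)))
  lo <- min(pre); hi <- max(pre)
  if (hi == lo) stop("no nuclei found: constant counterstain image")
  n01 <- (pre - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(n01), range = c(0, 1))
  mask <- n01 > thr
  mask <- EBImage::erode(EBImage::Image(mask * 1), .box3()) > 0.5
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  lab <- label8_cpp(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= params$min_nucleus_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("no nuclei found")
  mask
}

#' Separate touching cells by marker-controlled watershed
#'
#' Floods the distance-transform relief of the whole-cell mask from the
#' connected components of the nucleus mask, so each resulting label
#' contains exactly one nucleus seed and the labels partition the seeded
#' foreground. Cell regions without any seed are discarded with a warning;
#' cells touching the image border are dropped by default (a partially
#' imaged cell biases per-cell features).
#'
#' @param cellMask logical whole-cell foreground mask.
#' @param nucleiMask logical nucleus mask (seeds).
#' @param dropBorder drop labels touching the image border (default TRUE).
#' @return A \linkS4class{CompartmentMap}.
#' @export
separateCells <- function(cellMask, nucleiMask, dropBorder = TRUE) {
  stopifnot(identical(dim(cellMask), dim(nucleiMask)))
  cellMask <- cellMask | nucleiMask   # seeds must lie inside the foreground
  seeds <- label8_cpp(nucleiMask)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(cellMask * 1)))
  lab <- marker_watershed_cpp(-dm, seeds, cellMask)
  n_lost <- sum(unique(label8_cpp(cellMask & lab == 0L)) > 0L)
  if (n_lost > 0L)
    warning(n_lost, " foreground region(s) without a nucleus seed discarded")
  if (dropBorder) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    border <- border[border > 0L]
    if (length(border)) {
      warning(length(border), " border-touching cell(s) dropped")
      lab[lab %in% border] <- 0L
    }
  }
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  relab <- lab
  for (k in seq_along(ids)) relab[lab == ids[k]] <- k
  new("CompartmentMap", cellLabels = relab,
      nucleusMask = nucleiMask & relab > 0L,
      cellIds = seq_along(ids))
}

#' Segment discrete hybrid foci within one compartment
#'
#' The marker image is restricted to the region; for cytoplasm a white
#' top-hat (disc, \code{tophat_radius}) removes slowly varying background;
#' the local median map is computed and thresholded strictly above the third
#' quartile (Q3) of its values inside the region; candidate blobs are then
#' split into discrete foci by geodesic reconstruction: the regional maxima
#' of the median map (8-connected, h-maxima suppression of one quantization
#' step to merge plateau duplicates) act as markers and every candidate
#' pixel joins the influence zone of the marker whose flood reaches it
#' first. Area and intensities are measured on the original, un-preprocessed
#' marker image.
#'
#' A constant-signal region yields an empty set: Q3 equals the maximum and
#' the strictly-above rule selects nothing.
#'
#' @param marker marker-channel \linkS4class{Image2D} or matrix.
#' @param regionMask logical compartment mask (nonempty).
#' @param compartment "nucleus" or "cytoplasm".
#' @param params a \code{\link{segParams}} object.
#' @param cellId cell id recorded in the output (default NA).
#' @return A \linkS4class{FociSet} of class-"focus" objects.
#' @export
segmentFoci <- function(marker, regionMask, compartment = c("nucleus",
                        "cytoplasm"), params = segParams(), cellId = NA_integer_) {
  compartment <- match.arg(compartment)
  img <- .px(marker)
  stopifnot(identical(dim(img), dim(regionMask)))
  if (!any(regionMask)) stop("empty region")
  # work on the region's bounding box (padded) for speed; the region is
  # zeroed outside itself so the crop does not change any map value inside
  pad <- max(params$median_window, params$tophat_radius + 1L)
  rr <- range(which(rowSums(regionMask) > 0))
  cr <- range(which(colSums(regionMask) > 0))
  ys <- max(1L, rr[1L] - pad):min(nrow(img), rr[2L] + pad)
  xs <- max(1L, cr[1L] - pad):min(ncol(img), cr[2L] + pad)
  sub <- regionMask[ys, xs, drop = FALSE]
  work <- img[ys, xs, drop = FALSE]
  work[!sub] <- 0
  if (compartment == "cytoplasm") {
    brush <- EBImage::makeBrush(2L * params$tophat_radius + 1L, "disc")
    work <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(work), brush))
    work[!sub] <- 0
  }
  map <- median_filter_cpp(work, params$median_window)
  q3 <- stats::quantile(map[sub], 0.75, names = FALSE, type = 7)
  cand <- map > q3 & sub
  if (!any(cand)) return(emptyFociSet(dim(img)))
  # markers: regional maxima of the map (h-maxima, h = 1 quantization step)
  rec <- grey_reconstruct_cpp(map - 1, map)
  markers <- (map - rec) >= 1 & cand
  seeds <- label8_cpp(markers)
  lab_sub <- marker_watershed_cpp(-map, seeds, cand)
  lab <- matrix(0L, nrow(img), ncol(img))
  lab[ys, xs] <- lab_sub
  .fociFromLabels(lab, img, compartment, cellId)
}

# Build a FociSet from a label image, measuring on the original marker image.
.fociFromLabels <- function(lab, img, compartment, cellId) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  if (length(ids) == 0L) return(emptyFociSet(dim(img)))
  ny <- nrow(img)
  pix <- split(which(lab > 0L), lab[lab > 0L])[as.character(ids)]
  area <- lengths(pix)
  tot <- vapply(pix, function(p) sum(img[p]), numeric(1))
  cy <- vapply(pix, function(p) mean((p - 1L) %% ny), numeric(1))
  cx <- vapply(pix, function(p) mean((p - 1L) %/% ny), numeric(1))
  FociSet(
    objects = data.frame(id = seq_along(ids), cell_id = as.integer(cellId),
                         compartment = compartment, area = as.integer(area),
                         mean_intensity = tot / area, total_intensity = tot,
                         centroid_y = cy, centroid_x = cx,
                         object_class = "focus", stringsAsFactors = FALSE,
                         row.names = NULL),
    pixels = unname(pix), dim = dim(img))
}

#' Classify nuclear objects into foci and perinuclear/nucleolar clusters
#'
#' Objects whose area strictly exceeds the dimension criterion
#' (\code{cluster_area_threshold}) become clusters; a cluster with at least
#' one pixel 8-adjacent to the nuclear boundary (the morphological internal
#' gradient of the nucleus mask) is perinuclear, otherwise nucleolar.
#' Objects at or below the threshold keep class "focus".
#'
#' @param foci a \linkS4class{FociSet} with compartment "nucleus" only.
#' @param nucleusMask logical nucleus mask of the same cell.
#' @param params a \code{\link{segParams}} object.
#' @return The relabeled \linkS4class{FociSet}.
#' @export
classifyNuclearObjects <- function(foci, nucleusMask, params = segParams()) {
  stopifnot(is(foci, "FociSet"))
  df <- fociTable(foci)
  if (nrow(df) == 0L) return(foci)
  if (any(df$compartment != "nucleus"))
    stop("all objects must have compartment 'nucleus'")
  boundary <- nucleusMask &
    !(EBImage::erode(EBImage::Image(nucleusMask * 1), .box3()) > 0.5)
  # 8-adjacency to the boundary = intersection with its unit dilation
  zone <- EBImage::dilate(EBImage::Image(boundary * 1), .box3()) > 0.5
  pix <- fociPixels(foci)
  for (k in seq_len(nrow(df))) {
    if (df$area[k] > params$cluster_area_threshold) {
      df$object_class[k] <- if (any(zone[pix[[k]]]))
        "perinuclear_cluster" else "nucleolar_cluster"
    }
  }
  FociSet(df, pix, foci@dim)
}

# concatenate FociSets (shared image dim), reassigning object ids
.bindFoci <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L) stop("no foci sets to bind")
  df <- do.call(rbind, lapply(sets, fociTable))
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  FociSet(df, do.call(c, lapply(sets, fociPixels)), sets[[1L]]@dim)
}
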