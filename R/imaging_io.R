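# Image and table I/O. Multi-page grayscale TIFF in, CSV/PNG/TIFF out.

#' Read one channel of a multi-page TIFF z-stack
#'
#' Pages are interpreted either as one file per channel (\code{layout =
#' "file"}: all pages belong to the requested channel) or as interleaved
#' channels (\code{layout = "interleaved"}: page k belongs to channel
#' \code{(k - 1) \%\% nChannels + 1}). Which physical channel is the
#' counterstain and which the hybrid marker is always the caller's choice;
#' vendor metadata is never consulted. Pixel size comes from the caller
#' (acquisition metadata beyond pixel size is out of scope).
#'
#' @param path path to a readable multi-page grayscale TIFF.
#' @param channel 1-based channel index to extract.
#' @param nChannels number of interleaved channels in the file.
#' @param layout "file" (default) or "interleaved".
#' @param pixelSize micrometres per pixel side (default 0.1).
#' @param bitDepth nominal bit depth of the acquisition (default 12).
#' @param channelName tag stored in the result.
#' @return A \linkS4class{ChannelStack}.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(lapply(1:3, function(i) matrix(i / 255, 8, 8)), tf)
#' dim(voxels(loadStack(tf)))
#' @export
loadStack <- function(path, channel = 1L, nChannels = 1L,
                      layout = c("file", "interleaved"),
                      pixelSize = 0.1, bitDepth = 12L, channelName = "") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("unreadable TIFF: ", path, " (no pages)")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("non-grayscale page(s) in ", path, "; expected single-sample pages")
  channel <- as.integer(channel)
  if (layout == "interleaved") {
    nChannels <- as.integer(nChannels)
    if (channel < 1L || channel > nChannels)
      stop("channel ", channel, " not present (file has ", nChannels,
           " interleaved channels)")
    idx <- seq(channel, length(pages), by = nChannels)
    if (length(idx) == 0L) stop("channel ", channel, " not present in ", path)
    pages <- pages[idx]
  } else if (channel != 1L) {
    stop("channel ", channel, " not present: layout 'file' holds one channel")
  }
  d <- dim(pages[[1L]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    stop("pages of ", path, " differ in size")
  vox <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  ChannelStack(vox, bitDepth = bitDepth, pixelSize = pixelSize,
               channelName = channelName)
}

#' Maximum intensity projection of a z-stack
#'
#' Each output pixel is the maximum of that (y, x) position over all z
#' sections; pixel-size metadata is carried over.
#'
#' @param stack a \linkS4class{ChannelStack} with at least one section.
#' @return An \linkS4class{Image2D}.
#' @examples
#' cs <- ChannelStack(array(c(1, 4, 2, 1, 3, 0, 4, 9), c(2, 2, 2)))
#' pixels(maxIntensityProjection(cs))
#' @export
maxIntensityProjection <- function(stack) {
  stopifnot(is(stack, "ChannelStack"))
  v <- voxels(stack)
  if (dim(v)[1L] < 1L) stop("empty stack")
  out <- v[1L, , , drop = TRUE]
  if (dim(v)[1L] > 1L)
    for (z in 2:dim(v)[1L]) out <- pmax(out, v[z, , , drop = TRUE])
  Image2D(matrix(out, dim(v)[2L], dim(v)[3L]), pixelSize = pixelSize(stack))
}

# Stable column order of the per-cell feature table. Documented schema:
# densities are per pixel with a per-um^2 companion; undefined features
# (e.g. FGI of a cell without foci) are empty cells, never 0.
featureSchema <- function() {
  c("condition", "field", "cell_id", "compartment",
    "foci_count", "region_area_px", "foci_density_px",
    "foci_density_um2", "foci_mean_intensity", "fgi",
    "perinuclear_count", "perinuclear_density_px",
    "perinuclear_mean_intensity",
    "nucleolar_count", "nucleolar_density_px", "nucleolar_mean_intensity",
    paste0("ldi_pct_", 0:8))
}

#' Write the per-cell feature table as CSV
#'
#' One row per (cell, compartment); columns follow the stable schema of
#' \code{HybridFoci:::featureSchema()} (columns absent from \code{records}
#' are filled with missing values). Missing values are written as empty
#' cells. UTF-8, "." decimal separator.
#'
#' @param records non-empty data.frame of feature records.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeFeatureTable <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  schema <- featureSchema()
  for (col in setdiff(schema, names(records))) records[[col]] <- NA
  extra <- setdiff(names(records), schema)
  records <- records[, c(schema, extra), drop = FALSE]
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write ", path))
  on.exit(close(con))
  utils::write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a feature table written by writeFeatureTable
#'
#' @param path CSV path.
#' @return A data.frame with empty cells restored as NA.
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  encoding = "UTF-8")
}

#' Write a mask or label image as 16-bit single-page TIFF
#'
#' @param mask logical or integer matrix (labels up to 65535).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeMaskTIFF <- function(mask, path) {
  m <- mask
  storage.mode(m) <- "double"
  if (max(m) > 65535) stop("labels exceed the 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a mask/label image written by writeMaskTIFF
#'
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
readMaskTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
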