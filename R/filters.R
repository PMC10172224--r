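# Pixel-level preprocessing: local median maps, local contrast enhancement,
# histogram-mode thresholding and channel fusion.

# helpers to accept either Image2D or a bare matrix and answer in kind
.px <- function(x) if (is(x, "Image2D")) pixels(x) else x
.rewrap <- function(x, m) if (is(x, "Image2D")) Image2D(m, pixelSize(x)) else m

#' Local median map
#'
#' Each output pixel is the median of the square window centred on it;
#' borders are handled by edge replication. The map is the workhorse of both
#' nucleus and foci segmentation: it models the local background robustly
#' while leaving compact bright structures in place.
#'
#' @param image an \linkS4class{Image2D} or numeric matrix.
#' @param window odd window side in pixels, >= 3 and smaller than the image.
#' @return Same type as \code{image}.
#' @examples
#' m <- matrix(10, 5, 5); m[3, 3] <- 100
#' localMedianMap(m, 3)[3, 3]   # outlier removed
#' @export
localMedianMap <- function(image, window = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be an odd integer >= 3")
  m <- .px(image)
  if (window >= min(dim(m))) stop("window must be smaller than the image")
  .rewrap(image, median_filter_cpp(m, window))
}

#' Local contrast enhancement (CLAHE)
#'
#' Contrast-limited adaptive histogram equalization, rescaled back to the
#' input range. A constant image is returned unchanged (nothing to enhance).
#'
#' @param image an \linkS4class{Image2D} or numeric matrix.
#' @param tile number of tiles per side (>= 2).
#' @param clip clip limit (> 0), in multiples of the uniform bin height.
#' @return Same type as \code{image}, same value range.
#' @export
enhanceLocalContrast <- function(image, tile = 8L, clip = 2) {
  stopifnot(tile >= 2L, clip > 0)
  m <- .px(image)
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(image)
  # pad by edge replication to a multiple of the tile grid, equalize, crop
  tile <- as.integer(tile)
  py <- (tile - nrow(m) %% tile) %% tile
  px <- (tile - ncol(m) %% tile) %% tile
  mp <- m[c(seq_len(nrow(m)), rep(nrow(m), py)),
          c(seq_len(ncol(m)), rep(ncol(m), px)), drop = FALSE]
  eq <- EBImage::clahe(EBImage::Image(mp / hi), nx = tile, ny = tile,
                       limit = clip, keep.range = FALSE)
  eq <- EBImage::imageData(eq)[seq_len(nrow(m)), seq_len(ncol(m)), drop = FALSE]
  ehi <- max(eq)
  if (ehi == 0) return(image)
  # rescale into the image's intensity range [0, max]: contrast between
  # levels grows while the dtype range is respected
  .rewrap(image, eq / ehi * hi)
}

#' Threshold an image at its histogram mode
#'
#' Computes the intensity histogram (exact values for integer-valued images,
#' \code{bins} equal-width bins otherwise), finds the modal bin and returns
#' the pixels strictly above it as foreground. Intended for the channel
#' fusion image, whose mode is the (dominant) background level.
#'
#' @param image an \linkS4class{Image2D} or numeric matrix, non-constant.
#' @param bins number of bins for non-integer images (default 256).
#' @return Logical matrix (TRUE = foreground).
#' @export
thresholdAtHistogramMode <- function(image, bins = 256L) {
  m <- .px(image)
  lo <- min(m); hi <- max(m)
  if (hi == lo) stop("degenerate histogram: constant image")
  if (all(m == round(m))) {
    counts <- table(m)
    mode_val <- as.numeric(names(counts))[which.max(counts)]
    return(m > mode_val)
  }
  bins <- as.integer(bins)
  idx <- pmin(bins, 1L + floor((m - lo) / (hi - lo) * bins))
  counts <- tabulate(idx, nbins = bins)
  matrix(idx > which.max(counts), nrow(m), ncol(m))
}

#' Fuse two channels into one normalized image
#'
#' Min-max normalizes each channel, combines them per pixel with the chosen
#' rule and rescales the result to [0, 1]. The fused image drives whole-cell
#' foreground detection: the counterstain dominates nuclei while diffuse
#' staining of either channel reveals the cytoplasm.
#'
#' @param dapi,marker \linkS4class{Image2D} or matrices of identical shape.
#' @param rule "max" (default) or "sum".
#' @return Same type as \code{dapi}, values in [0, 1].
#' @export
fuseChannels <- function(dapi, marker, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  a <- .px(dapi); b <- .px(marker)
  if (!identical(dim(a), dim(b))) stop("channel shape mismatch")
  norm01 <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi == lo) matrix(0, nrow(m), ncol(m)) else (m - lo) / (hi - lo)
  }
  f <- switch(rule, max = pmax(norm01(a), norm01(b)),
              sum = norm01(a) + norm01(b))
  hi <- max(f)
  if (hi > 0) f <- f / hi
  .rewrap(dapi, f)
}
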