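# Local density analysis: density distribution maps (DDM) over a minimal
# 3x3 search window, LDI histograms and colormap rendering.

#' Compute the density distribution map of a binary mask
#'
#' Every foreground pixel receives a local density index (LDI): the number
#' of foreground pixels among its 8 neighbors in the 3x3 window, from 0 for
#' isolated pixels to 8 for fully connected ones. The image border is
#' treated as background, so a mask touching the border reports lower LDI
#' there. Background pixels carry NA.
#'
#' @param mask logical (or 0/1 numeric) 2-D matrix.
#' @return A \linkS4class{DensityMap}.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' ldi(computeDDM(m))[3, 3]   # isolated pixel -> 0
#' @export
computeDDM <- function(mask) {
  stopifnot(length(dim(mask)) == 2L)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  new("DensityMap", ldi = ldi_count_cpp(m), mask = m)
}

#' LDI histogram of a density map
#'
#' Percentage of foreground pixels at each local density index 0..8.
#'
#' @param ddm a \linkS4class{DensityMap} with nonempty foreground.
#' @return Named numeric vector ldi_pct_0 .. ldi_pct_8 summing to 100.
#' @export
ldiHistogram <- function(ddm) {
  stopifnot(is(ddm, "DensityMap"))
  vals <- ldi(ddm)[ddm@mask]
  if (length(vals) == 0L) stop("empty foreground: LDI histogram undefined")
  pct <- 100 * tabulate(vals + 1L, nbins = 9L) / length(vals)
  names(pct) <- paste0("ldi_pct_", 0:8)
  pct
}

# Discrete 9-entry palette for LDI 0..8 (Okabe-Ito derived, colorblind-safe,
# ordered from cool sparse to warm dense), background black.
ldiPalette <- function() {
  c("#332288", "#0072B2", "#56B4E9", "#44AA99", "#009E73",
    "#F0E442", "#E69F00", "#D55E00", "#CC0000")
}

#' Render a density map as an RGB colormap
#'
#' Deterministic rendering: each LDI value 0..8 maps to one entry of the
#' documented discrete palette; background is black. Optionally writes a
#' PNG.
#'
#' @param ddm a \linkS4class{DensityMap}.
#' @param path optional PNG output path.
#' @return Numeric array (y, x, 3) in [0, 1], invisibly when \code{path} is
#'   given.
#' @export
renderDDM <- function(ddm, path = NULL) {
  stopifnot(is(ddm, "DensityMap"))
  pal <- grDevices::col2rgb(ldiPalette()) / 255
  d <- dim(ddm@mask)
  img <- array(0, c(d, 3L))
  idx <- which(ddm@mask)
  if (length(idx)) {
    v <- ldi(ddm)[idx] + 1L
    for (ch in 1:3) {
      plane <- matrix(0, d[1L], d[2L])
      plane[idx] <- pal[ch, v]
      img[, , ch] <- plane
    }
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
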