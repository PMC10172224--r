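# Regional descriptors per cell and compartment: foci density, intensity,
# granulation index (FGI) and nuclear cluster features.

.fociOnly <- function(foci) {
  df <- fociTable(foci)
  df[df$object_class == "focus", , drop = FALSE]
}

#' Foci density of a region
#'
#' Count of class-"focus" objects divided by the region area. The exact
#' value is per pixel; the per-square-micrometre companion uses
#' \code{pixelSize} (1 px = pixelSize^2 um^2).
#'
#' @param foci a \linkS4class{FociSet}.
#' @param regionArea region area in pixels (> 0).
#' @param pixelSize optional micrometres per pixel side for the companion.
#' @return Named numeric: \code{per_px}, and \code{per_um2} when
#'   \code{pixelSize} is given.
#' @examples
#' fociDensity(HybridFoci:::emptyFociSet(c(10, 10)), 1000, pixelSize = 0.1)
#' @export
fociDensity <- function(foci, regionArea, pixelSize = NULL) {
  if (regionArea <= 0) stop("region area must be positive")
  d <- c(per_px = nrow(.fociOnly(foci)) / regionArea)
  if (!is.null(pixelSize)) d["per_um2"] <- d[["per_px"]] / pixelSize^2
  d
}

#' Mean foci intensity of a region
#'
#' Mean over class-"focus" objects of the per-focus mean pixel intensity
#' (arbitrary units of the original marker image). Area-independent by
#' construction; the integrated (total-intensity) alternative is available
#' behind \code{integrated = TRUE}.
#'
#' @param foci a \linkS4class{FociSet}.
#' @param integrated average per-focus total intensities instead of means.
#' @return Numeric, or NA when the set holds no foci (undefined, not 0).
#' @export
fociIntensity <- function(foci, integrated = FALSE) {
  df <- .fociOnly(foci)
  if (nrow(df) == 0L) return(NA_real_)
  if (integrated) mean(df$total_intensity) else mean(df$mean_intensity)
}

#' Foci granulation index (FGI)
#'
#' Percentage of regional class-"focus" objects having 1-pixel area; the
#' descriptor of foci occurring at the resolution limit. Clusters are
#' excluded by definition. Depends on areas only, so it is invariant to any
#' intensity rescaling of the marker channel.
#'
#' @param foci a \linkS4class{FociSet}.
#' @return Percentage in [0, 100], or NA for an empty set (undefined).
#' @examples
#' computeFGI(HybridFoci:::emptyFociSet(c(8, 8)))  # NA
#' @export
computeFGI <- function(foci) {
  df <- .fociOnly(foci)
  if (nrow(df) == 0L) return(NA_real_)
  100 * sum(df$area == 1L) / nrow(df)
}

#' Nuclear cluster features
#'
#' Per cluster class (perinuclear, nucleolar): object count, count
#' normalized by the whole-nucleus area, and mean of per-cluster mean
#' intensities (NA when the class is absent).
#'
#' @param foci a \linkS4class{FociSet} of nuclear objects.
#' @param nucleusArea nucleus area in pixels (> 0).
#' @return Named list with perinuclear_count, perinuclear_density_px,
#'   perinuclear_mean_intensity and the nucleolar counterparts.
#' @export
clusterFeatures <- function(foci, nucleusArea) {
  if (nucleusArea <= 0) stop("nucleus area must be positive")
  df <- fociTable(foci)
  one <- function(cls) {
    sub <- df[df$object_class == cls, , drop = FALSE]
    list(count = nrow(sub), density = nrow(sub) / nucleusArea,
         intensity = if (nrow(sub)) mean(sub$mean_intensity) else NA_real_)
  }
  p <- one("perinuclear_cluster"); n <- one("nucleolar_cluster")
  list(perinuclear_count = p$count, perinuclear_density_px = p$density,
       perinuclear_mean_intensity = p$intensity,
       nucleolar_count = n$count, nucleolar_density_px = n$density,
       nucleolar_mean_intensity = n$intensity)
}

#' Feature records for one cell
#'
#' Assembles the per-compartment feature rows (nucleus and cytoplasm) of
#' one cell from its classified foci set. Cluster fields are reported on
#' nucleus rows only; undefined features are NA (missing), never 0.
#'
#' @param foci classified \linkS4class{FociSet} of this cell (both
#'   compartments).
#' @param nucleusArea,cytoArea compartment areas in pixels.
#' @param cellId cell identifier.
#' @param pixelSize micrometres per pixel side.
#' @return A 2-row data.frame following the feature-table schema.
#' @export
cellFeatures <- function(foci, nucleusArea, cytoArea, cellId,
                         pixelSize = 0.1) {
  df <- fociTable(foci)
  row_for <- function(comp, area) {
    sub <- df[df$compartment == comp, , drop = FALSE]
    fs <- FociSet(sub, fociPixels(foci)[df$compartment == comp], foci@dim)
    dens <- fociDensity(fs, area, pixelSize)
    out <- data.frame(cell_id = cellId, compartment = comp,
                      foci_count = nrow(.fociOnly(fs)),
                      region_area_px = area,
                      foci_density_px = dens[["per_px"]],
                      foci_density_um2 = dens[["per_um2"]],
                      foci_mean_intensity = fociIntensity(fs),
                      fgi = computeFGI(fs), stringsAsFactors = FALSE)
    if (comp == "nucleus") {
      cl <- clusterFeatures(fs, area)
      out <- cbind(out, as.data.frame(cl[c("perinuclear_count",
        "perinuclear_density_px", "perinuclear_mean_intensity",
        "nucleolar_count", "nucleolar_density_px",
        "nucleolar_mean_intensity")]))
    } else {
      out[c("perinuclear_count", "perinuclear_density_px",
            "perinuclear_mean_intensity", "nucleolar_count",
            "nucleolar_density_px", "nucleolar_mean_intensity")] <- NA
    }
    out
  }
  rbind(row_for("nucleus", nucleusArea), row_for("cytoplasm", cytoArea))
}
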