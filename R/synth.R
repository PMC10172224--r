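# Deterministic synthetic two-channel fields of view with full ground
# truth: textured elliptical nuclei in the counterstain channel, Gaussian
# foci / resolution-limited point sources / nuclear clusters in the marker
# channel, Poisson shot noise plus Gaussian read noise.
#
# The default regime emulates offset-subtracted confocal acquisitions with
# frame accumulation: compartments are quantization-dark (diffuse flux well
# below one count per pixel) and foci are photon-limited, with peak SNR
# peak/sqrt(peak) ~ 8 at the default peak of 64 counts. This is the regime
# in which Q3-of-median-map thresholding isolates discrete objects.

#' Field-of-view specification for the synthetic generator
#'
#' All geometry is in pixels; intensities are photon counts. The seed fully
#' determines the rendered field. Per-compartment focus counts are Poisson
#' draws truncated at a packing cap (\code{caps}), emulating the physical
#' limit on how many objects fit a compartment.
#'
#' @param image_size c(ny, nx) image size.
#' @param n_cells number of cells to place.
#' @param nucleus_axes range of nucleus semi-axes (px).
#' @param cyto_expand cytoplasm = nucleus dilated by this radius (px).
#' @param foci_lambda named c(nucleus=, cytoplasm=) Poisson means of focus
#'   counts per compartment.
#' @param p_impulse probability that a focus is a resolution-limited
#'   1-pixel-class point source.
#' @param focus_sigma_nuc,focus_sigma_cyto Gaussian sigma ranges (px) of
#'   extended foci per compartment.
#' @param focus_peak_mean,focus_peak_sd named c(nucleus=, cytoplasm=) peak
#'   photon counts (normal, truncated at \code{peak_floor}).
#' @param peak_floor lower truncation of peak draws.
#' @param cluster_lambda named c(perinuclear=, nucleolar=) Poisson means of
#'   nuclear cluster counts.
#' @param cluster_sigma,cluster_peak_mean,cluster_peak_sd cluster shape and
#'   brightness.
#' @param perinuclear_depth perinuclear cluster centres lie in the depth
#'   band 4..perinuclear_depth (px) inside the nuclear boundary, deep
#'   enough that the conservatively eroded nucleus mask retains the bulk
#'   of the cluster.
#' @param nucleolar_depth nucleolar cluster centres lie at least this deep.
#' @param focus_margin_nuc,focus_margin_cyto minimum depth of focus centres
#'   inside their compartment.
#' @param min_sep minimum centre separation between foci of one cell (px);
#'   clusters additionally keep their full supports apart.
#' @param caps named packing caps c(foci_nuc=, foci_cyto=, peri=, nucl=).
#' @param dapi_nucleus_level,dapi_cyto_level,dapi_texture_amp counterstain
#'   rendering: nuclear plateau (with multiplicative low-frequency texture
#'   of relative amplitude \code{dapi_texture_amp}) and diffuse cytoplasmic
#'   spill.
#' @param marker_diffuse diffuse marker flux inside cells (counts/px).
#' @param background field background flux (counts/px).
#' @param poisson_noise apply Poisson shot noise to all mean counts.
#' @param read_sd Gaussian read noise s.d. (counts), rounded to integers.
#' @param nz number of z sections emitted when writing stacks.
#' @param pixel_size,bit_depth acquisition metadata.
#' @param seed integer seed, fully determines the field.
#' @param max_tries dart-throwing retries per object before an
#'   overcrowding error.
#' @return A list of class "FieldSpec".
#' @export
fieldSpec <- function(image_size = c(224L, 224L), n_cells = 4L,
                      nucleus_axes = c(18, 22), cyto_expand = 10L,
                      foci_lambda = c(nucleus = 4, cytoplasm = 3),
                      p_impulse = 0.25,
                      focus_sigma_nuc = c(0.7, 1.0),
                      focus_sigma_cyto = c(0.6, 0.9),
                      focus_peak_mean = c(nucleus = 64, cytoplasm = 64),
                      focus_peak_sd = c(nucleus = 10, cytoplasm = 10),
                      peak_floor = 30,
                      cluster_lambda = c(perinuclear = 0.8, nucleolar = 0.5),
                      cluster_sigma = c(2.0, 2.6),
                      cluster_peak_mean = 200, cluster_peak_sd = 25,
                      perinuclear_depth = 8, nucleolar_depth = 13,
                      focus_margin_nuc = 6, focus_margin_cyto = 4,
                      min_sep = 5,
                      caps = c(foci_nuc = 6L, foci_cyto = 5L, peri = 2L,
                               nucl = 1L),
                      dapi_nucleus_level = 100, dapi_cyto_level = 8,
                      dapi_texture_amp = 0.2, marker_diffuse = 0.02,
                      background = 0, poisson_noise = TRUE, read_sd = 0.2,
                      nz = 3L, pixel_size = 0.1, bit_depth = 12L,
                      seed = 1L, max_tries = 400L) {
  spec <- as.list(environment())
  stopifnot(spec$n_cells >= 1L, all(spec$foci_lambda >= 0),
            all(spec$cluster_lambda >= 0), spec$p_impulse >= 0,
            spec$p_impulse <= 1, spec$nz >= 1L, spec$pixel_size > 0)
  class(spec) <- "FieldSpec"
  spec
}

.truncPeak <- function(n, mean, sd, floor) pmax(floor, stats::rnorm(n, mean, sd))

# render an isotropic Gaussian spot truncated at 3*sigma, clipped to `clip`
.renderSpot <- function(img, clip, cy, cx, sigma, peak) {
  r <- ceiling(3 * sigma)
  ys <- max(1L, cy - r):min(nrow(img), cy + r)
  xs <- max(1L, cx - r):min(ncol(img), cx + r)
  for (x in xs) {
    d2 <- (ys - cy)^2 + (x - cx)^2
    keep <- d2 <= (3 * sigma)^2 & clip[ys, x]
    img[ys[keep], x] <- img[ys[keep], x] +
      peak * exp(-d2[keep] / (2 * sigma^2))
  }
  img
}

# resolution-limited point source: peak at the centre plus a 4-neighbor
# skirt at peak/4 (diagonals zero); its local median map has exactly
# one-pixel support, so it segments to area 1 at zero noise
.renderImpulse <- function(img, clip, cy, cx, peak) {
  at <- function(y, x, v) {
    if (y >= 1 && y <= nrow(img) && x >= 1 && x <= ncol(img) && clip[y, x])
      img[y, x] <<- img[y, x] + v
  }
  at(cy, cx, peak)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    at(cy + d[1], cx + d[2], peak / 4)
  img
}

# Dart-throwing placement with per-object keepout radii: a new centre must
# keep max(keepout_existing, keepout_new) from every placed centre. When the
# candidate set is empty while objects are requested the compartment cannot
# host the request at all (overcrowding error); when individual darts run
# out of retries the remaining objects of that batch are dropped, so the
# ground truth always lists exactly what was rendered.
.placeCenters <- function(candidates, n, ny, placed, keep_new, max_tries,
                          what) {
  if (n > 0L && length(candidates) == 0L)
    stop("cannot place requested ", what, " (overcrowding)")
  ys <- integer(0); xs <- integer(0)
  for (k in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      p <- candidates[sample.int(length(candidates), 1L)]
      py <- (p - 1L) %% ny + 1L
      px <- (p - 1L) %/% ny + 1L
      ally <- c(placed$y, ys); allx <- c(placed$x, xs)
      allk <- c(placed$keep, rep(keep_new, length(ys)))
      if (length(ally) == 0L ||
          all((ally - py)^2 + (allx - px)^2 >= pmax(allk, keep_new)^2)) {
        ys <- c(ys, py); xs <- c(xs, px)
        break
      }
    }
  }
  list(y = ys, x = xs)
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders the counterstain (DAPI-like) and marker (S9.6-like) channels of
#' \code{spec} and returns them with the full ground truth. The same seed
#' yields a byte-identical field.
#'
#' @param spec a \code{\link{fieldSpec}}.
#' @return A list: \code{dapi}, \code{marker} (\linkS4class{Image2D}),
#'   \code{truth} (list with nucleusLabels, cellLabels matrices and an
#'   objects data.frame: cell_id, compartment, object_class, is_impulse,
#'   center_y/center_x (0-based), sigma, peak), and \code{spec}.
#' @examples
#' f <- generateField(fieldSpec(n_cells = 2, image_size = c(128L, 128L),
#'                              seed = 7))
#' nrow(f$truth$objects)
#' @export
generateField <- function(spec) {
  stopifnot(inherits(spec, "FieldSpec"))
  set.seed(spec$seed)
  ny <- spec$image_size[1L]; nx <- spec$image_size[2L]
  amax <- spec$nucleus_axes[2L]
  margin <- ceiling(amax + spec$cyto_expand + 3)
  if (2 * margin >= min(ny, nx)) stop("image too small for the requested cells")
  sep_cells <- 2 * (amax + spec$cyto_expand) + 2

  cy <- numeric(0); cx <- numeric(0)
  tries <- 0L
  while (length(cy) < spec$n_cells) {
    if ((tries <- tries + 1L) > spec$max_tries * spec$n_cells)
      stop("cannot place requested cells (overcrowding)")
    py <- stats::runif(1, margin, ny - margin)
    px <- stats::runif(1, margin, nx - margin)
    if (length(cy) == 0L || min((cy - py)^2 + (cx - px)^2) >= sep_cells^2) {
      cy <- c(cy, py); cx <- c(cx, px)
    }
  }

  nucleusLabels <- matrix(0L, ny, nx)
  dapi_mean <- matrix(spec$background, ny, nx)
  yg <- matrix(seq_len(ny), ny, nx)
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (k in seq_len(spec$n_cells)) {
    a <- stats::runif(1, spec$nucleus_axes[1L], spec$nucleus_axes[2L])
    b <- stats::runif(1, spec$nucleus_axes[1L], spec$nucleus_axes[2L])
    th <- stats::runif(1, 0, pi)
    dy <- yg - cy[k]; dx <- xg - cx[k]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    nucleusLabels[inside] <- k
    fx <- stats::runif(1, 0.02, 0.06) * sample(c(-1, 1), 1)
    fy <- stats::runif(1, 0.02, 0.06) * sample(c(-1, 1), 1)
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- 0.5 + 0.5 * sin(2 * pi * (fx * xg + fy * yg) + ph)
    amp <- spec$dapi_texture_amp
    dapi_mean[inside] <- spec$dapi_nucleus_level *
      (1 - amp / 2 + amp * tex[inside])
  }

  brush <- EBImage::makeBrush(2L * spec$cyto_expand + 1L, "disc")
  cellLabels <- matrix(0L, ny, nx)
  for (k in seq_len(spec$n_cells)) {
    cell <- EBImage::dilate(EBImage::Image((nucleusLabels == k) * 1), brush) > 0.5
    cellLabels[cell] <- k
  }
  cyto <- cellLabels > 0L & nucleusLabels == 0L
  dapi_mean[cyto] <- spec$dapi_cyto_level

  depth_nuc <- EBImage::imageData(EBImage::distmap(
    EBImage::Image((nucleusLabels > 0L) * 1)))
  depth_cell <- EBImage::imageData(EBImage::distmap(
    EBImage::Image((cellLabels > 0L) * 1)))
  dist_nuc <- EBImage::imageData(EBImage::distmap(
    EBImage::Image((nucleusLabels == 0L) * 1)))

  marker_mean <- matrix(spec$background, ny, nx)
  marker_mean[cellLabels > 0L] <- marker_mean[cellLabels > 0L] +
    spec$marker_diffuse
  objects <- list()

  for (k in seq_len(spec$n_cells)) {
    nuc_k <- nucleusLabels == k
    cyto_k <- cellLabels == k & !nuc_k
    placed <- list(y = numeric(0), x = numeric(0), keep = numeric(0))
    add_obj <- function(comp, cls, impulse, y, x, sigma, peak) {
      objects[[length(objects) + 1L]] <<- data.frame(
        cell_id = k, compartment = comp, object_class = cls,
        is_impulse = impulse, center_y = y - 1L, center_x = x - 1L,
        sigma = sigma, peak = peak, stringsAsFactors = FALSE)
    }

    # nuclear clusters first (largest objects)
    n_peri <- min(stats::rpois(1, spec$cluster_lambda[["perinuclear"]]),
                  spec$caps[["peri"]])
    n_nucl <- min(stats::rpois(1, spec$cluster_lambda[["nucleolar"]]),
                  spec$caps[["nucl"]])
    band <- which(nuc_k & depth_nuc >= 4 & depth_nuc <= spec$perinuclear_depth)
    core <- which(nuc_k & depth_nuc >= spec$nucleolar_depth)
    keep_cluster <- 3 * spec$cluster_sigma[2L] + 3
    for (type in c("perinuclear_cluster", "nucleolar_cluster")) {
      n <- if (type == "perinuclear_cluster") n_peri else n_nucl
      cand <- if (type == "perinuclear_cluster") band else core
      if (n == 0L) next
      pl <- .placeCenters(cand, n, ny, placed, keep_cluster, spec$max_tries,
                          "clusters")
      for (i in seq_along(pl$y)) {
        sg <- stats::runif(1, spec$cluster_sigma[1L], spec$cluster_sigma[2L])
        pk <- .truncPeak(1, spec$cluster_peak_mean, spec$cluster_peak_sd,
                         spec$peak_floor * 2)
        marker_mean <- .renderSpot(marker_mean, nuc_k, pl$y[i], pl$x[i], sg, pk)
        add_obj("nucleus", type, FALSE, pl$y[i], pl$x[i], sg, pk)
      }
      placed$y <- c(placed$y, pl$y); placed$x <- c(placed$x, pl$x)
      placed$keep <- c(placed$keep, rep(keep_cluster, length(pl$y)))
    }

    # foci per compartment
    for (comp in c("nucleus", "cytoplasm")) {
      lam <- spec$foci_lambda[[comp]]
      cap <- spec$caps[[if (comp == "nucleus") "foci_nuc" else "foci_cyto"]]
      n <- min(stats::rpois(1, lam), cap)
      if (n == 0L) next
      cand <- if (comp == "nucleus")
        which(nuc_k & depth_nuc >= spec$focus_margin_nuc)
      else
        which(cyto_k & depth_cell >= spec$focus_margin_cyto &
              dist_nuc >= 3)
      pl <- .placeCenters(cand, n, ny, placed, spec$min_sep, spec$max_tries,
                          "foci")
      clip <- if (comp == "nucleus") nuc_k else cyto_k
      srange <- if (comp == "nucleus") spec$focus_sigma_nuc
                else spec$focus_sigma_cyto
      for (i in seq_along(pl$y)) {
        impulse <- stats::runif(1) < spec$p_impulse
        pk <- .truncPeak(1, spec$focus_peak_mean[[comp]],
                         spec$focus_peak_sd[[comp]], spec$peak_floor)
        if (impulse) {
          marker_mean <- .renderImpulse(marker_mean, clip, pl$y[i], pl$x[i], pk)
          add_obj(comp, "focus", TRUE, pl$y[i], pl$x[i], 0, pk)
        } else {
          sg <- stats::runif(1, srange[1L], srange[2L])
          marker_mean <- .renderSpot(marker_mean, clip, pl$y[i], pl$x[i], sg, pk)
          add_obj(comp, "focus", FALSE, pl$y[i], pl$x[i], sg, pk)
        }
      }
      placed$y <- c(placed$y, pl$y); placed$x <- c(placed$x, pl$x)
      placed$keep <- c(placed$keep, rep(spec$min_sep, length(pl$y)))
    }
  }

  addNoise <- function(mean_img) {
    out <- if (spec$poisson_noise)
      matrix(stats::rpois(length(mean_img), mean_img), ny, nx)
    else round(mean_img)
    if (spec$read_sd > 0)
      out <- out + round(matrix(stats::rnorm(length(out), 0, spec$read_sd),
                                ny, nx))
    out[out < 0] <- 0
    out
  }
  dapi <- addNoise(dapi_mean)
  marker <- addNoise(marker_mean)

  obj_df <- if (length(objects)) do.call(rbind, objects) else
    data.frame(cell_id = integer(), compartment = character(),
               object_class = character(), is_impulse = logical(),
               center_y = integer(), center_x = integer(),
               sigma = numeric(), peak = numeric(), stringsAsFactors = FALSE)

  list(dapi = Image2D(dapi, spec$pixel_size),
       marker = Image2D(marker, spec$pixel_size),
       truth = list(nucleusLabels = nucleusLabels, cellLabels = cellLabels,
                    objects = obj_df),
       spec = spec)
}

# split a 2-D image into nz sections whose per-pixel maximum reconstructs
# the image exactly (each pixel's value goes to one random section)
.splitStack <- function(img, nz) {
  m <- .px(img)
  vox <- array(0, c(nz, nrow(m), ncol(m)))
  if (nz == 1L) { vox[1L, , ] <- m; } else {
    pick <- matrix(sample.int(nz, length(m), replace = TRUE), nrow(m), ncol(m))
    for (z in seq_len(nz)) {
      s <- m; s[pick != z] <- 0
      vox[z, , ] <- s
    }
  }
  vox
}

#' Write a synthetic field to disk in the package's TIFF dialect
#'
#' Emits per-channel multi-page TIFF z-stacks (whose maximum intensity
#' projection reconstructs the generated 2-D images exactly), 16-bit mask
#' TIFFs of the ground-truth labels, and the truth object table as CSV.
#'
#' @param field a \code{\link{generateField}} result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
writeField <- function(field, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- 2^16 - 1
  paths <- c(dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
             marker = file.path(dir, paste0(prefix, "_s96.tif")),
             nuclei = file.path(dir, paste0(prefix, "_nuclei_mask.tif")),
             cells = file.path(dir, paste0(prefix, "_cell_mask.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")))
  for (ch in c("dapi", "marker")) {
    vox <- .splitStack(field[[ch]], field$spec$nz)
    pages <- lapply(seq_len(dim(vox)[1L]), function(z)
      matrix(vox[z, , ] / scale, dim(vox)[2L], dim(vox)[3L]))
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L)
  }
  writeMaskTIFF(field$truth$nucleusLabels, paths[["nuclei"]])
  writeMaskTIFF(field$truth$cellLabels, paths[["cells"]])
  utils::write.csv(field$truth$objects, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Paper-inspired condition profiles for the generator
#'
#' Named parameter overrides of the base \code{\link{fieldSpec}} emulating
#' the direction (not the magnitude) of the treatment effects: a hyperbaric-
#' oxygen-like arm doubles nuclear focus peak intensity and raises the
#' perinuclear (and mildly the nucleolar) cluster rate; a hypoxia-like arm
#' raises focus counts with dimmer peaks and tighter packing; an
#' irradiation-like arm lowers both counts and intensity.
#'
#' @return Named list of profiles, including the mandatory control.
#' @export
conditionProfiles <- function() {
  list(
    control = list(),
    hbo_like = list(focus_peak_mean = c(nucleus = 128, cytoplasm = 80),
                    cluster_lambda = c(perinuclear = 2.2, nucleolar = 0.9)),
    hypox_like = list(foci_lambda = c(nucleus = 5.4, cytoplasm = 4.1),
                      focus_peak_mean = c(nucleus = 77, cytoplasm = 70),
                      min_sep = 4,
                      cluster_lambda = c(perinuclear = 1.6, nucleolar = 0.8)),
    ir_like = list(foci_lambda = c(nucleus = 2.2, cytoplasm = 1.6),
                   focus_peak_mean = c(nucleus = 35, cytoplasm = 35),
                   cluster_lambda = c(perinuclear = 0.4, nucleolar = 0.25))
  )
}

#' Generate a multi-condition synthetic dataset
#'
#' Applies per-condition overrides to a base \code{\link{fieldSpec}} and
#' renders \code{n_fields} fields per condition with deterministically
#' derived per-field seeds. The profile list must contain a
#' \code{control} entry.
#'
#' @param profiles named list of override lists (see
#'   \code{\link{conditionProfiles}}); must include "control".
#' @param n_fields fields per condition.
#' @param seed master seed; per-field seeds are derived from it.
#' @param base base \code{\link{fieldSpec}}.
#' @param dir optional output directory; when given, every field is written
#'   via \code{\link{writeField}} along with a manifest CSV.
#' @return A list: \code{fields} (condition -> list of fields) and
#'   \code{manifest} (data.frame condition, field, seed).
#' @export
generateConditionSet <- function(profiles, n_fields, seed = 1L,
                                 base = fieldSpec(), dir = NULL) {
  if (!"control" %in% names(profiles))
    stop("profiles must include a 'control' condition")
  fields <- list()
  manifest <- list()
  for (i in seq_along(profiles)) {
    cond <- names(profiles)[i]
    over <- profiles[[i]]
    cfields <- vector("list", n_fields)
    for (j in seq_len(n_fields)) {
      sp <- utils::modifyList(base, over)
      class(sp) <- "FieldSpec"
      sp$seed <- as.integer((as.numeric(seed) * 1009 + i * 99991 +
                             j * 7919) %% 2147483629)
      cfields[[j]] <- generateField(sp)
      manifest[[length(manifest) + 1L]] <-
        data.frame(condition = cond, field = j, seed = sp$seed,
                   stringsAsFactors = FALSE)
      if (!is.null(dir))
        writeField(cfields[[j]], file.path(dir, cond),
                   prefix = sprintf("field%03d", j))
    }
    fields[[cond]] <- cfields
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(fields = fields, manifest = manifest)
}
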