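# End-to-end orchestration: images -> compartments -> foci -> features ->
# density maps -> group statistics, with config validation and a
# reproducible output tree.

#' Analyze one two-channel field
#'
#' Runs the full single-field pipeline on projected 2-D images: nucleus
#' segmentation from the counterstain, whole-cell foreground by
#' histogram-mode thresholding of the channel fusion image, watershed cell
#' separation, per-compartment foci segmentation with nuclear-object
#' classification, per-cell feature records and per-cell density
#' distribution maps (computed on the union of the cell's foci pixels over
#' both compartments, with LDI percentages appended to the feature rows of
#' that cell).
#'
#' @param dapi,marker \linkS4class{Image2D} projections of the two channels.
#' @param params a \code{\link{segParams}} object.
#' @return A list: \code{features} (data.frame, two rows per cell),
#'   \code{map} (\linkS4class{CompartmentMap}), \code{foci} (named list of
#'   per-cell classified \linkS4class{FociSet}s), \code{ddm} (named list of
#'   per-cell \linkS4class{DensityMap}s).
#' @export
analyzeField <- function(dapi, marker, params = segParams()) {
  nuclei <- segmentNuclei(dapi, params)
  fused <- fuseChannels(dapi, marker, params$fusion_rule)
  cellMask <- thresholdAtHistogramMode(fused)
  map <- separateCells(cellMask, nuclei)
  feats <- list(); fociList <- list(); ddmList <- list()
  for (cell in cellIds(map)) {
    nuc <- nucleusOf(map, cell)
    cyt <- cytoplasmOf(map, cell)
    fn <- segmentFoci(marker, nuc, "nucleus", params, cellId = cell)
    fn <- classifyNuclearObjects(fn, nuc, params)
    fc <- if (any(cyt))
      segmentFoci(marker, cyt, "cytoplasm", params, cellId = cell)
    else emptyFociSet(dim(.px(marker)))
    all_f <- if (length(fn) + length(fc) > 0L)
      .bindFoci(list(fn, fc)) else emptyFociSet(dim(.px(marker)))
    fr <- cellFeatures(all_f, sum(nuc), sum(cyt), cell,
                       pixelSize = pixelSize(marker))
    # per-cell DDM over the union of this cell's foci pixels
    fmask <- matrix(FALSE, nrow(.px(marker)), ncol(.px(marker)))
    fmask[unlist(fociPixels(all_f))] <- TRUE
    dm <- computeDDM(fmask)
    if (any(fmask)) {
      pct <- ldiHistogram(dm)
      for (nm in names(pct)) fr[[nm]] <- pct[[nm]]
    } else {
      fr[paste0("ldi_pct_", 0:8)] <- NA_real_
    }
    key <- as.character(cell)
    feats[[key]] <- fr; fociList[[key]] <- all_f; ddmList[[key]] <- dm
  }
  list(features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
       map = map, foci = fociList, ddm = ddmList)
}

#' Validate a pipeline run configuration
#'
#' Checks the config for missing input files, out-of-range parameters and
#' (when statistics are enabled) the presence of the control condition.
#' Returns the violations instead of stopping so callers can report all
#' problems at once.
#'
#' @param config a run configuration list (see \code{\link{runPipeline}}).
#' @return Character vector of violations; empty when the config is valid.
#' @export
validateConfig <- function(config) {
  bad <- character(0)
  if (is.null(config[["output_dir"]])) bad <- c(bad, "output_dir missing")
  man <- config[["manifest"]]
  if (is.null(man) || !nrow(man) ||
      !all(c("condition", "dapi", "marker") %in% names(man))) {
    bad <- c(bad, "manifest must have columns condition, dapi, marker")
  } else {
    missing <- !file.exists(c(man$dapi, man$marker))
    if (any(missing))
      bad <- c(bad, paste("missing input file:",
                          c(man$dapi, man$marker)[missing]))
    stats_on <- is.null(config[["statistics"]]) || isTRUE(config[["statistics"]])
    ctrl <- if (is.null(config[["control"]])) "control" else config[["control"]]
    if (stats_on && !ctrl %in% man$condition)
      bad <- c(bad, paste0("control condition '", ctrl,
                           "' absent from manifest"))
  }
  p <- config[["params"]]
  if (!is.null(p)) {
    chk <- tryCatch({ do.call(segParams, p); character(0) },
                    error = function(e) paste("invalid params:",
                                              conditionMessage(e)))
    bad <- c(bad, chk)
  }
  bad
}

#' Run the full pipeline over a dataset manifest
#'
#' Stages: validation, per-field segmentation + feature extraction +
#' density mapping, then group statistics of every non-control condition
#' against the control with Bonferroni family size \code{m} (default: the
#' number of treatment arms). The output tree contains per-field 16-bit
#' mask TIFFs, DDM PNGs, the per-cell feature CSV, the comparison CSV, a
#' variance table CSV and a run log recording the package version, the
#' verbatim config and the dimension criterion and family size in use.
#' Reruns with the same config produce identical tabular outputs.
#'
#' @param config list with entries: \code{manifest} (data.frame: condition,
#'   dapi, marker file paths), \code{output_dir}, optional \code{params}
#'   (list passed to \code{\link{segParams}}), \code{control} (default
#'   "control"), \code{m} (Bonferroni family size), \code{channel},
#'   \code{n_channels}, \code{layout} (passed to \code{\link{loadStack}}
#'   for the marker/dapi files), \code{pixel_size}, \code{statistics}
#'   (logical). May also be a path to a JSON file with these entries.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the feature table, comparison table and
#'   variance table.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  if (is.data.frame(config[["manifest"]]) || is.list(config[["manifest"]]))
    config[["manifest"]] <- as.data.frame(config[["manifest"]],
                                     stringsAsFactors = FALSE)
  bad <- validateConfig(config)
  if (length(bad))
    stop("validation failed:\n  ", paste(bad, collapse = "\n  "))
  out <- config[["output_dir"]]
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(segParams, if (is.null(config[["params"]])) list()
                    else config[["params"]])
  ctrl <- if (is.null(config[["control"]])) "control" else config[["control"]]
  px <- if (is.null(config[["pixel_size"]])) 0.1 else config[["pixel_size"]]
  note <- function(...) if (!quiet) message(...)

  man <- config[["manifest"]]
  feats <- list()
  for (r in seq_len(nrow(man))) {
    note("segmentation: ", man$condition[r], " field ", r)
    dapi <- maxIntensityProjection(loadStack(man$dapi[r], pixelSize = px,
                                             channelName = "DAPI"))
    marker <- maxIntensityProjection(loadStack(man$marker[r], pixelSize = px,
                                               channelName = "S9.6"))
    res <- tryCatch(analyzeField(dapi, marker, params),
                    error = function(e) stop("stage 'segmentation' failed on ",
                                             man$dapi[r], ": ",
                                             conditionMessage(e)))
    fr <- res$features
    fr$condition <- man$condition[r]
    fr$field <- r
    feats[[r]] <- fr
    tag <- sprintf("%s_f%03d", man$condition[r], r)
    writeMaskTIFF(cellLabels(res$map), file.path(out, paste0(tag, "_cells.tif")))
    writeMaskTIFF(res$map@nucleusMask * 1L,
                  file.path(out, paste0(tag, "_nuclei.tif")))
    for (cell in names(res$ddm))
      renderDDM(res$ddm[[cell]],
                file.path(out, sprintf("%s_cell%s_ddm.png", tag, cell)))
  }
  features <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
  writeFeatureTable(features, file.path(out, "features.csv"))

  feature_cols <- c("foci_density_px", "foci_mean_intensity", "fgi",
                    "perinuclear_count", "perinuclear_mean_intensity",
                    "nucleolar_count", "nucleolar_mean_intensity")
  comparisons <- NULL
  vtab <- NULL
  if (is.null(config[["statistics"]]) || isTRUE(config[["statistics"]])) {
    note("statistics: comparisons vs ", ctrl)
    arms <- setdiff(unique(man$condition), ctrl)
    m <- if (is.null(config[["m"]])) max(1L, length(arms)) else as.integer(config[["m"]])
    rows <- list()
    for (comp in c("nucleus", "cytoplasm")) {
      sub <- features[features$compartment == comp, , drop = FALSE]
      for (f in feature_cols) {
        if (comp == "cytoplasm" && grepl("nuclear|nucleolar", f)) next
        cx <- sub[[f]][sub$condition == ctrl]
        for (arm in arms) {
          tx <- sub[[f]][sub$condition == arm]
          if (sum(!is.na(cx)) < 3L || sum(!is.na(tx)) < 3L) next
          st <- compareGroups(cx, tx, m = m)
          st$feature <- f; st$compartment <- comp; st$condition <- arm
          rows[[length(rows) + 1L]] <- st
        }
      }
    }
    if (length(rows)) {
      comparisons <- do.call(rbind, rows)
      utils::write.csv(comparisons, file.path(out, "comparisons.csv"),
                       row.names = FALSE)
    }
    vcols <- intersect(c("foci_density_px", "fgi", "foci_mean_intensity"),
                       names(features))
    nucv <- varianceTable(features[features$compartment == "nucleus", ], vcols)
    cytv <- varianceTable(features[features$compartment == "cytoplasm", ], vcols)
    names(nucv)[-(1:2)] <- paste0(names(nucv)[-(1:2)], "_nucleus")
    names(cytv)[-(1:2)] <- paste0(names(cytv)[-(1:2)], "_cytoplasm")
    vtab <- merge(nucv, cytv[, -2], by = "condition", sort = FALSE)
    utils::write.csv(vtab, file.path(out, "variance_table.csv"),
                     row.names = FALSE)
  }

  log_lines <- c(
    paste0("HybridFoci ", as.character(utils::packageVersion("HybridFoci"))),
    paste0("cluster_area_threshold: ", params$cluster_area_threshold),
    paste0("bonferroni_m: ", if (exists("m", inherits = FALSE)) m else NA),
    paste0("nuclear_mode: ", params$nuclear_mode),
    "config:",
    jsonlite::toJSON(config[setdiff(names(config), "manifest")],
                     auto_unbox = TRUE, null = "null"))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(features = features, comparisons = comparisons,
                 variance_table = vtab))
}
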