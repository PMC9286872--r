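## Orchestration: reproducible simulate / quantify runs over standard-format
## files, driven by a single JSON config. Every threshold and default used is
## echoed into the run report so reported numbers are auditable functions of
## (inputs, config, seed).

pkgVersion <- function()
  as.character(utils::packageVersion("repquant"))

#' Write a synthetic dataset to disk
#'
#' Generates a section (\code{\link{generateSection}}) and a FISH dot field
#' (\code{\link{generateFishField}}) and writes: \code{images.tiff} (pages
#' nuclei, autofluorescence, reporter, marker), \code{zones.tiff} +
#' legend, \code{cells.csv} and \code{dots.csv} (ground truth),
#' \code{fish_cells.csv}, and \code{config.json} echoing every generator
#' parameter including the pixel size. Deterministic per seed; the output
#' directory is created if missing.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param outputDir output directory
#' @return invisibly, a list of the written paths
#' @export
runSimulate <- function(spec, outputDir) {
  validObject(spec)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  sim <- generateSection(spec)
  ff <- generateFishField(spec)
  paths <- list(
    images = file.path(outputDir, "images.tiff"),
    zones = file.path(outputDir, "zones.tiff"),
    cells = file.path(outputDir, "cells.csv"),
    dots = file.path(outputDir, "dots.csv"),
    fish_cells = file.path(outputDir, "fish_cells.csv"),
    config = file.path(outputDir, "config.json"))
  order <- writeImageStack(sim$image, paths$images)
  writeZoneMap(sim$truth@zoneMap, paths$zones)
  utils::write.csv(sim$truth@cells, paths$cells, row.names = FALSE)
  utils::write.csv(ff$dots, paths$dots, row.names = FALSE)
  utils::write.csv(ff$cells, paths$fish_cells, row.names = FALSE)
  cfg <- list(
    generator = "repquant", version = pkgVersion(),
    channel_order = order, pixel_size_um = spec@pixelSize,
    image_shape = spec@imageShape,
    zone_band_fractions = spec@zoneBandFractions,
    n_cells_per_zone = spec@nCellsPerZone,
    cell_diameter_range_um = spec@cellDiameterRange,
    cell_intensity = spec@cellIntensity,
    tubule_fraction = spec@tubuleFraction,
    marker_overlap_prob = spec@markerOverlapProb,
    marker_extra_area_frac = spec@markerExtraAreaFrac,
    fish_count_mean = spec@fishCountMean,
    fish_count_dispersion = spec@fishCountDispersion,
    dot_jitter_sd_um = spec@dotJitterSd, noise_sd = spec@noiseSd,
    seed = spec@seed)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Quantify a dataset end to end
#'
#' Chains the analysis stages over a dataset on disk: reporter-cell detection
#' and tissue area, zone assignment and the per-zone density report,
#' marker colocalization (per configured marker threshold), FISH dot
#' clustering + co-labelling when a dot table is given, and whole-kidney
#' extrapolation when a geometry is given. A failing stage aborts with the
#' stage named. Warnings (no signal, empty tissue, undefined densities) are
#' collected as machine-readable report fields.
#'
#' @param config a list or path to a JSON file with fields: \code{images}
#'   (TIFF path), \code{channel_order}, \code{pixel_size_um}; optional
#'   \code{zones} (label TIFF), \code{dots} (CSV), \code{markers} (list of
#'   \code{{name, threshold}}), \code{params} (DetectionParams fields),
#'   \code{cluster_radius_um}, \code{match_radius_um}, \code{min_overlap_px},
#'   \code{geometry} (\code{{length_mm, width_mm, depth_mm,
#'   section_thickness_um}}), \code{output_dir}
#' @return a run-report list (also written as \code{report.json} with CSVs to
#'   \code{output_dir} when configured)
#' @export
runQuantify <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  need <- c("images", "channel_order", "pixel_size_um")
  if (!all(need %in% names(config)))
    stop("config requires fields: ", paste(need, collapse = ", "))
  warnings <- list()
  grab <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings[[length(warnings) + 1L]] <<- list(stage = stage,
          message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  p <- config$params
  params <- detectionParams(
    minDiameter = p$min_diameter_um %||% 10,
    backgroundRadius = p$background_radius_um %||% 50,
    connectivity = p$connectivity %||% 8L,
    gaussianSigma = p$gaussian_sigma_um %||% 10,
    closeRadius = p$close_radius_um %||% 20)

  stack <- grab("read", readImageStack(config$images, config$channel_order,
                                       config$pixel_size_um))
  det <- grab("detection", detectCells(stack, params = params))
  tissue <- if ("nuclei" %in% channelNames(stack))
    grab("tissue_mask", computeTissueMask(stack, params = params)) else NULL

  report <- list(software = "repquant", version = pkgVersion(),
                 config = config,
                 params = list(min_diameter_um = params@minDiameter,
                               background_radius_um = params@backgroundRadius,
                               connectivity = params@connectivity,
                               gaussian_sigma_um = params@gaussianSigma,
                               close_radius_um = params@closeRadius),
                 n_detections = nCells(det),
                 no_signal = det@noSignal,
                 tissue_area_mm2 = if (!is.null(tissue)) maskArea(tissue))

  zreport <- NULL
  if (!is.null(config$zones)) {
    zones <- grab("zonation", readZoneMap(config$zones, config$pixel_size_um))
    det <- grab("zonation", assignZones(det, zones))
    zreport <- grab("zonation", zoneDensityReport(det, zones))
    report$zone_report <- zreport
    report$n_unassigned <- attr(zreport, "n_unassigned")
    report$whole_slice_density <- attr(zreport, "whole_slice_density")
    if (!is.null(config$geometry)) {
      g <- config$geometry
      geom <- kidneyGeometry(g$length_mm, g$width_mm, g$depth_mm,
                             g$section_thickness_um %||% 12)
      dens <- attr(zreport, "whole_slice_density")
      report$whole_kidney <- grab("extrapolation",
                                  estimateTotalCells(dens, geom))
    }
  }

  if (!is.null(config$markers) && "marker" %in% channelNames(stack) &&
      !is.null(tissue)) {
    marks <- config$markers
    if (!is.null(names(marks)) || is.data.frame(marks))
      marks <- if (is.data.frame(marks))
        split(marks, seq_len(nrow(marks))) else list(marks)
    coloc <- lapply(marks, function(mk) {
      mm <- grab("colocalization",
                 markerMask(stack, mk$threshold, mk$name %||% "marker"))
      det <<- grab("colocalization",
                   callDoublePositives(det, mm,
                                       config$min_overlap_px %||% 10L))
      s <- doublePositiveSummary(det)
      s$positive_area_fraction <- grab("colocalization",
                                       positiveAreaFraction(mm, tissue))
      s
    })
    report$colocalization <- coloc
  } else if (!is.null(config$markers)) {
    warnings[[length(warnings) + 1L]] <- list(stage = "colocalization",
      message = "marker config given but no marker channel/tissue; skipped")
  }

  if (!is.null(config$dots)) {
    dtab <- grab("fish", readDotTable(config$dots))
    fc <- grab("fish", clusterDots(dtab, config$cluster_radius_um %||% 5))
    fc <- grab("fish", tagFishCells(fc, det,
                                    config$match_radius_um %||% 5))
    comp <- grab("fish", compositionStats(fc, det))
    counts <- cellTable(fc)$n_dots
    report$fish <- c(comp, list(
      n_clusters = nCells(fc),
      top_decile_share = if (length(counts) > 0 && any(counts > 0))
        contributorSlices(contributionCurve(counts), 0.1) else NA_real_))
    fishOut <- fc
  } else fishOut <- NULL

  report$warnings <- warnings
  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    writeDetectionsCsv(det, file.path(out, "detections.csv"))
    if (!is.null(zreport))
      utils::write.csv(zreport, file.path(out, "zone_report.csv"),
                       row.names = FALSE)
    if (!is.null(fishOut))
      utils::write.csv(cellTable(fishOut), file.path(out, "fish_cells.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
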