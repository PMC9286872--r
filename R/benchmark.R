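#' Match detections to planted ground-truth cells
#'
#' Greedy one-to-one nearest matching between detected and planted centroids
#' within \code{maxDist} micrometres. Recall is matched/planted, precision
#' matched/detected.
#'
#' @param detections a \linkS4class{CellDetections}
#' @param truthCells ground-truth cell data.frame with \code{x_um},
#'   \code{y_um} (e.g. \code{truth@cells} from \code{\link{generateSection}})
#' @param maxDist matching distance, micrometres
#' @return list: nMatched, recall, precision, pairs (matrix of det/truth row
#'   indices)
#' @export
matchDetections <- function(detections, truthCells, maxDist = 5) {
  stopifnot(is(detections, "CellDetections"))
  tab <- detections@table
  matchPoints(cbind(tab$x_um, tab$y_um),
              cbind(truthCells$x_um, truthCells$y_um), maxDist)
}

# TRUE for planted cells whose marginPx-neighbourhood lies entirely within
# one zone (used to restrict zone-accuracy scoring to interior cells).
zoneInteriorCells <- function(truthCells, zones, marginPx = 2L) {
  lab <- zones@labels
  nr <- nrow(lab); nc <- ncol(lab)
  vapply(seq_len(nrow(truthCells)), function(i) {
    r0 <- truthCells$row_px[i] + 1L
    c0 <- truthCells$col_px[i] + 1L
    px <- diskIndices(r0, c0, marginPx, nr, nc)
    length(unique(lab[px])) == 1L
  }, logical(1))
}

#' Detection and zonation recovery benchmark
#'
#' Runs the full planted-cell recovery study: for each seed a synthetic
#' section is generated, cells are detected, zones assigned, detections are
#' matched to ground truth at \code{matchDist}, and recovery metrics
#' recorded. Zone-assignment accuracy is scored on matched cells whose
#' planted centroid lies at least \code{zoneMarginPx} pixels inside a single
#' zone (cells straddling a boundary have no uniquely correct label). The
#' transcript-contribution recovery re-generates a FISH field per seed,
#' clusters the dots and reads the top-decile transcript share off the
#' contribution curve.
#'
#' @param spec a \linkS4class{SyntheticSpec}; its seed slot is replaced by
#'   each entry of \code{seeds}
#' @param seeds integer vector of seeds (at least one)
#' @param params a \linkS4class{DetectionParams}
#' @param matchDist ground-truth matching distance, micrometres
#' @param zoneMarginPx interior margin for zone scoring, pixels
#' @param outputDir optional directory; when given, metrics are written to
#'   \code{benchmark.csv} there
#' @return data.frame with one row per seed: seed, n_planted, n_detected,
#'   recall, precision, zone_accuracy, top_decile_share
#' @export
runBenchmark <- function(spec, seeds, params = detectionParams(),
                         matchDist = 5, zoneMarginPx = 2L, outputDir = NULL) {
  if (length(seeds) == 0L) stop("at least one seed is required")
  rows <- lapply(seeds, function(sd) {
    sp <- spec; sp@seed <- as.integer(sd)
    sim <- generateSection(sp)
    det <- detectCells(sim$image, params = params)
    det <- assignZones(det, sim$truth@zoneMap)
    m <- matchDetections(det, sim$truth@cells, maxDist = matchDist)
    interior <- zoneInteriorCells(sim$truth@cells, sim$truth@zoneMap,
                                  zoneMarginPx)
    zacc <- NA_real_
    if (m$nMatched > 0) {
      useRows <- m$pairs[interior[m$pairs[, "truth"]], , drop = FALSE]
      if (nrow(useRows) > 0)
        zacc <- mean(det@table$zone[useRows[, "det"]] ==
                     sim$truth@cells$zone[useRows[, "truth"]])
    }
    ff <- generateFishField(sp)
    share <- NA_real_
    if (nrow(ff$dots) > 0) {
      fc <- clusterDots(ff$dots)
      share <- contributorSlices(contributionCurve(cellTable(fc)$n_dots), 0.1)
    }
    data.frame(seed = sd, n_planted = nrow(sim$truth@cells),
               n_detected = nCells(det), recall = m$recall,
               precision = m$precision, zone_accuracy = zacc,
               top_decile_share = share)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outputDir, "benchmark.csv"),
                     row.names = FALSE)
  }
  out
}

#' 2D-to-3D extrapolation recovery study
#'
#' Plants a uniform 3D cell field in the kidney ellipsoid, cuts and renders
#' serial sections (\code{\link{generateSerialSections}}), then runs the
#' measurement chain on each section: reporter-cell detection, tissue area
#' from the nuclei channel, areal density, and ellipsoid extrapolation. The
#' per-section whole-kidney estimates are averaged.
#'
#' @param geometry a \linkS4class{KidneyGeometry}
#' @param nTotalCells planted whole-kidney total
#' @param nSections number of sections
#' @param params a \linkS4class{DetectionParams}
#' @param seed integer seed
#' @param ... further arguments to \code{\link{generateSerialSections}}
#' @return list: planted, recovered (mean estimate), ratio
#'   (recovered/planted), perSection data.frame
#' @export
extrapolationRecovery <- function(geometry, nTotalCells, nSections = 6,
                                  params = detectionParams(), seed = 1L, ...) {
  sim <- generateSerialSections(geometry, nTotalCells, nSections, seed = seed,
                                ...)
  per <- lapply(seq_along(sim$stacks), function(s) {
    stack <- sim$stacks[[s]]
    det <- detectCells(stack, params = params)
    tm <- computeTissueMask(stack, params = params)
    dens <- nCells(det) / maskArea(tm)
    est <- estimateTotalCells(dens, geometry)
    data.frame(section = s, n_planted_slab = sim$countsInSlab[s],
               n_detected = nCells(det), tissue_mm2 = maskArea(tm),
               density_cells_mm2 = dens, total_estimate = est$total)
  })
  per <- do.call(rbind, per)
  recovered <- mean(per$total_estimate)
  list(planted = nTotalCells, recovered = recovered,
       ratio = recovered / nTotalCells, perSection = per)
}
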