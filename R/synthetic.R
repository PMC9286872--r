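#' Synthetic section specification
#'
#' Constructor for \linkS4class{SyntheticSpec}; see the class documentation
#' for the meaning and defaults of every field. Cells are planted per zone of
#' a concentric elliptical zone map (outermost band = cortex), on interstitial
#' (non-tubule) pixels, by rejection sampling that forbids overlap between
#' cells.
#'
#' @param imageShape image size in pixels (rows, cols)
#' @param pixelSize micrometres per pixel
#' @param zoneBandFractions radial band-width fractions, outermost first,
#'   summing to 1 (cortex, OSOM, ISOM, IM, papilla)
#' @param nCellsPerZone planted reporter cells per zone (same order)
#' @param cellDiameterRange cell diameter range, micrometres
#' @param cellIntensity planted 8-bit cell intensity
#' @param tubuleFraction fraction of tissue covered by autofluorescent tubules
#' @param markerOverlapProb probability a planted cell is marker-positive
#' @param markerExtraAreaFrac marker-positive tissue fraction outside cells
#' @param fishCountMean,fishCountDispersion negative-binomial mean and size of
#'   the per-cell transcript count distribution
#' @param dotJitterSd FISH dot scatter SD, micrometres
#' @param noiseSd Gaussian noise SD, 8-bit levels
#' @param seed integer seed driving all generator randomness
#' @return a validated \linkS4class{SyntheticSpec}
#' @examples
#' syntheticSpec(nCellsPerZone = c(0, 50, 0, 0, 0), seed = 2)
#' @export
syntheticSpec <- function(imageShape = c(1024L, 1024L), pixelSize = 2,
                          zoneBandFractions = c(0.35, 0.15, 0.20, 0.20, 0.10),
                          nCellsPerZone = c(45L, 120L, 75L, 40L, 20L),
                          cellDiameterRange = c(12, 20), cellIntensity = 200,
                          tubuleFraction = 0.3, markerOverlapProb = 0.25,
                          markerExtraAreaFrac = 0.02, fishCountMean = 5,
                          fishCountDispersion = 1.636, dotJitterSd = 1.5,
                          noiseSd = 8, seed = 1L) {
  new("SyntheticSpec", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, zoneBandFractions = zoneBandFractions,
      nCellsPerZone = as.integer(nCellsPerZone),
      cellDiameterRange = cellDiameterRange, cellIntensity = cellIntensity,
      tubuleFraction = tubuleFraction, markerOverlapProb = markerOverlapProb,
      markerExtraAreaFrac = markerExtraAreaFrac, fishCountMean = fishCountMean,
      fishCountDispersion = fishCountDispersion, dotJitterSd = dotJitterSd,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# Concentric elliptical zone banding of the tissue ellipse: normalized
# elliptical radius split into 5 annuli with the given radial-width fractions,
# outermost first. Returns list(labels, re, tissue).
ellipticalZoneMap <- function(nr, nc, fractions) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  br <- 0.45 * nr; bc <- 0.45 * nc
  re <- sqrt(outer(((1:nr - cy) / br)^2, ((1:nc - cx) / bc)^2, "+"))
  tissue <- re <= 1
  labels <- matrix(0L, nr, nc)
  upper <- c(1, 1 - cumsum(fractions)[1:4])
  lower <- c(1 - cumsum(fractions)[1:4], -1)
  for (k in 1:5)
    labels[re <= upper[k] & re > lower[k]] <- k
  list(labels = labels, re = re, tissue = tissue)
}

emptyTruthCells <- function() {
  data.frame(id = integer(0), row_px = numeric(0), col_px = numeric(0),
             x_um = numeric(0), y_um = numeric(0), diameter_um = numeric(0),
             zone = character(0), marker_positive = logical(0),
             fish_count = integer(0))
}

#' Generate a ground-truth-labelled synthetic kidney section
#'
#' Renders a 4-channel section image (nuclei, autofluorescence, reporter,
#' marker) with exhaustive ground truth. The tissue is an ellipse banded into
#' the five renal compartments; autofluorescent tubules are random disks
#' covering \code{tubuleFraction} of the tissue; reporter cells are disks of
#' the stated diameter and intensity planted on interstitial pixels of their
#' zone without mutual overlap (bounded rejection sampling; an unplaceable
#' request raises an error reporting the shortfall); marker-positive cells
#' (Bernoulli \code{markerOverlapProb}) are painted into the marker channel
#' together with extra marker area away from cells; every channel finally
#' receives Gaussian noise of SD \code{noiseSd}. Per-cell transcript counts
#' are drawn from the negative binomial. Deterministic for a fixed seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @return list with elements \code{image} (\linkS4class{ImageStack}) and
#'   \code{truth} (\linkS4class{GroundTruth})
#' @examples
#' sim <- generateSection(syntheticSpec(seed = 11))
#' sim$image
#' table(sim$truth@cells$zone)
#' @export
generateSection <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    nr <- spec@imageShape[1]; nc <- spec@imageShape[2]; ps <- spec@pixelSize
    zm <- ellipticalZoneMap(nr, nc, spec@zoneBandFractions)
    tissue <- zm$tissue; labels <- zm$labels
    tissueIdx <- which(tissue)

    ## tubules: random disks on tissue until the target coverage is reached
    tub <- matrix(FALSE, nr, nc)
    target <- spec@tubuleFraction * length(tissueIdx)
    covered <- 0
    iter <- 0L
    while (covered < target && iter < 5000L) {
      iter <- iter + 1L
      ctr <- tissueIdx[sample.int(length(tissueIdx), 1L)]
      r0 <- ((ctr - 1L) %% nr) + 1L
      c0 <- ((ctr - 1L) %/% nr) + 1L
      px <- diskIndices(r0, c0, stats::runif(1, 10, 25) / ps, nr, nc)
      px <- px[tissue[px] & !tub[px]]
      tub[px] <- TRUE
      covered <- covered + length(px)
    }

    ## cell placement: per zone, rejection sampling on interstitial pixels
    lo <- spec@cellDiameterRange[1]; hi <- spec@cellDiameterRange[2]
    accR <- numeric(0); accC <- numeric(0); accD <- numeric(0)
    accZ <- integer(0)
    for (z in 1:5) {
      nz <- spec@nCellsPerZone[z]
      if (nz == 0L) next
      elig <- which(labels == z & !tub)
      if (length(elig) == 0L)
        stop("zone ", ZONE_NAMES[z], " has no eligible interstitial pixels")
      placed <- 0L; attempts <- 0L
      while (placed < nz && attempts < 200L * nz) {
        attempts <- attempts + 1L
        idx <- elig[sample.int(length(elig), 1L)]
        r0 <- ((idx - 1L) %% nr) + 1L
        c0 <- ((idx - 1L) %/% nr) + 1L
        d <- stats::runif(1, lo, hi)
        if (length(accR) > 0) {
          sep <- sqrt((accR - r0)^2 + (accC - c0)^2) * ps
          if (any(sep < (accD + d) / 2 + 3 * ps)) next
        }
        accR <- c(accR, r0); accC <- c(accC, c0)
        accD <- c(accD, d); accZ <- c(accZ, z)
        placed <- placed + 1L
      }
      if (placed < nz)
        stop(errorCondition(
          paste0("could not place requested cells without overlap in zone ",
                 ZONE_NAMES[z], ": shortfall ", nz - placed, " of ", nz),
          class = "repquant_placement_shortfall"))
    }
    nCellsTot <- length(accR)

    markerPos <- if (nCellsTot > 0)
      stats::runif(nCellsTot) < spec@markerOverlapProb else logical(0)
    fishCounts <- if (nCellsTot > 0)
      stats::rnbinom(nCellsTot, mu = spec@fishCountMean,
                     size = spec@fishCountDispersion) else integer(0)

    ## render channels
    nuclei <- tissue * 120
    auto <- tissue * 30
    auto[tub] <- 140
    reporter <- matrix(0, nr, nc)
    marker <- matrix(0, nr, nc)
    cellPx <- vector("list", nCellsTot)
    for (i in seq_len(nCellsTot)) {
      px <- diskIndices(accR[i], accC[i], (accD[i] / 2) / ps, nr, nc)
      cellPx[[i]] <- px
      reporter[px] <- spec@cellIntensity
      if (markerPos[i]) marker[px] <- 180
    }
    ## extra marker-positive area, kept away from planted cells
    extraTarget <- spec@markerExtraAreaFrac * length(tissueIdx)
    covered <- 0; iter <- 0L
    maxCellRad <- if (nCellsTot > 0) max(accD) / 2 else 0
    while (covered < extraTarget && iter < 5000L) {
      iter <- iter + 1L
      ctr <- tissueIdx[sample.int(length(tissueIdx), 1L)]
      r0 <- ((ctr - 1L) %% nr) + 1L
      c0 <- ((ctr - 1L) %/% nr) + 1L
      rad <- stats::runif(1, 5, 15) / ps
      if (nCellsTot > 0) {
        sep <- sqrt((accR - r0)^2 + (accC - c0)^2) * ps
        if (any(sep < maxCellRad + rad * ps + 5)) next
      }
      px <- diskIndices(r0, c0, rad, nr, nc)
      px <- px[tissue[px]]
      covered <- covered + sum(marker[px] == 0)
      marker[px] <- 180
    }
    channels <- list(nuclei = nuclei, autofluorescence = auto,
                     reporter = reporter, marker = marker)
    if (spec@noiseSd > 0)
      channels <- lapply(channels, function(ch)
        ch + matrix(stats::rnorm(nr * nc, 0, spec@noiseSd), nr, nc))
    channels <- lapply(channels, clamp8bit)

    cells <- if (nCellsTot > 0)
      data.frame(id = seq_len(nCellsTot), row_px = accR - 1, col_px = accC - 1,
                 x_um = (accC - 1) * ps, y_um = (accR - 1) * ps,
                 diameter_um = accD, zone = ZONE_NAMES[accZ],
                 marker_positive = markerPos,
                 fish_count = as.integer(fishCounts))
    else emptyTruthCells()

    img <- new("ImageStack", channels = channels, pixelSize = ps, bitDepth = 8L)
    truth <- new("GroundTruth", cells = cells,
                 dots = data.frame(x_um = numeric(0), y_um = numeric(0),
                                   cell_id = integer(0)),
                 zoneMap = new("ZoneMap", labels = labels, pixelSize = ps),
                 tissueMask = tissue, tubuleMask = tub)
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic single-molecule FISH dot field
#'
#' Plants cells in the section frame, draws a transcript count per cell from
#' the over-dispersed negative binomial, and scatters that many dots around
#' each cell centroid with Gaussian jitter of SD \code{dotJitterSd}. With
#' \code{separable = TRUE} (the default) cells sit on a jittered grid with
#' spacing 5x the clustering radius and dot jitter is truncated at half the
#' radius, so single-linkage clustering at \code{clusterRadius} provably
#' yields exactly one cluster per dot-bearing planted cell (intra-cell dot
#' spacing <= radius, inter-cell nearest-dot spacing > radius). A cell count
#' that cannot be placed separably in the frame raises an error.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param nCells number of cells to plant (default: sum of
#'   \code{nCellsPerZone})
#' @param clusterRadius the downstream clustering radius, micrometres
#' @param separable enforce the cluster-separability contract
#' @return list with \code{dots} (data.frame x_um, y_um, cell_id, channel) and
#'   \code{cells} (data.frame id, x_um, y_um, fish_count)
#' @examples
#' ff <- generateFishField(syntheticSpec(seed = 3), nCells = 100)
#' mean(ff$cells$fish_count)
#' @export
generateFishField <- function(spec, nCells = sum(spec@nCellsPerZone),
                              clusterRadius = 5, separable = TRUE) {
  validObject(spec)
  stopifnot(clusterRadius > 0, nCells >= 0)
  withSeed(spec@seed, {
    width <- spec@imageShape[2] * spec@pixelSize
    height <- spec@imageShape[1] * spec@pixelSize
    if (nCells == 0L)
      return(list(dots = data.frame(x_um = numeric(0), y_um = numeric(0),
                                    cell_id = integer(0),
                                    channel = character(0)),
                  cells = data.frame(id = integer(0), x_um = numeric(0),
                                     y_um = numeric(0),
                                     fish_count = integer(0))))
    if (separable) {
      spacing <- 5 * clusterRadius
      gx <- seq(spacing / 2, width - spacing / 2, by = spacing)
      gy <- seq(spacing / 2, height - spacing / 2, by = spacing)
      if (length(gx) * length(gy) < nCells)
        stop(errorCondition(
          paste0("cell spacing makes separable placement impossible: grid ",
                 "capacity ", length(gx) * length(gy), " < ", nCells),
          class = "repquant_separability_impossible"))
      slots <- sample.int(length(gx) * length(gy), nCells)
      cxs <- gx[((slots - 1L) %% length(gx)) + 1L] +
        stats::runif(nCells, -clusterRadius / 2, clusterRadius / 2)
      cys <- gy[((slots - 1L) %/% length(gx)) + 1L] +
        stats::runif(nCells, -clusterRadius / 2, clusterRadius / 2)
    } else {
      cxs <- stats::runif(nCells, 0, width)
      cys <- stats::runif(nCells, 0, height)
    }
    counts <- stats::rnbinom(nCells, mu = spec@fishCountMean,
                             size = spec@fishCountDispersion)
    # truncated Gaussian jitter: dot stays within clusterRadius/2 of its cell
    jitterOne <- function() {
      repeat {
        j <- stats::rnorm(2, 0, max(spec@dotJitterSd, 1e-6))
        if (!separable || sqrt(sum(j^2)) <= clusterRadius / 2) return(j)
      }
    }
    dx <- numeric(0); dy <- numeric(0); did <- integer(0)
    for (i in seq_len(nCells)) {
      for (k in seq_len(counts[i])) {
        j <- jitterOne()
        dx <- c(dx, cxs[i] + j[1]); dy <- c(dy, cys[i] + j[2])
        did <- c(did, i)
      }
    }
    list(dots = data.frame(x_um = dx, y_um = dy, cell_id = did,
                           channel = rep("Epo", length(dx))),
         cells = data.frame(id = seq_len(nCells), x_um = cxs, y_um = cys,
                            fish_count = as.integer(counts)))
  })
}

#' Generate a carboxyhaemoglobin washout time series
#'
#' Linear decline from \code{s0} at slope \code{slope} (\%/min), clamped at
#' \code{baseline}, with optional Gaussian noise. Deterministic for a fixed
#' seed.
#'
#' @param s0 CO-Hb saturation at t = 0, percent
#' @param baseline baseline CO-Hb saturation, percent
#' @param slope decline rate, percent per minute (must be negative)
#' @param times sample times in minutes
#' @param noiseSd Gaussian noise SD in percent saturation
#' @param seed integer seed
#' @return data.frame(time_min, co_sat_pct) with the baseline attached as
#'   attribute \code{baseline}
#' @examples
#' generateWashoutSeries(54.8, 4.57, -1.0, times = c(0, 10, 20))
#' @export
generateWashoutSeries <- function(s0, baseline, slope, times,
                                  noiseSd = 0, seed = 1L) {
  if (slope >= 0) stop("slope must be negative for a washout")
  if (s0 <= baseline) stop("s0 must exceed baseline")
  if (is.unsorted(times, strictly = TRUE)) stop("times must strictly increase")
  vals <- pmax(baseline, s0 + slope * times)
  if (noiseSd > 0)
    vals <- withSeed(seed, vals + stats::rnorm(length(times), 0, noiseSd))
  out <- data.frame(time_min = times, co_sat_pct = vals)
  attr(out, "baseline") <- baseline
  out
}

#' Simulate serial sections through a 3D cell field
#'
#' Builds the oracle for the 2D-to-3D extrapolation: \code{nTotalCells} cells
#' are placed uniformly at random inside the kidney ellipsoid, sections of the
#' geometry's thickness are cut at evenly spaced depths within
#' \code{zSpanFraction} of the half-depth, and each section is rendered as a
#' nuclei + reporter image (cells whose centre falls inside the slab appear as
#' disks). Running detection, density and ellipsoid extrapolation on these
#' sections should recover the planted total.
#'
#' @param geometry a \linkS4class{KidneyGeometry}
#' @param nTotalCells planted whole-kidney cell count
#' @param nSections number of sections to cut
#' @param pixelSize micrometres per pixel of the rendered sections
#' @param cellDiameterRange,cellIntensity,noiseSd rendering parameters as in
#'   \code{\link{syntheticSpec}}
#' @param zSpanFraction sections are cut at depths within this fraction of the
#'   half-depth (away from the poles, where tiny cross-sections make single
#'   sections statistically useless)
#' @param seed integer seed
#' @return list: \code{stacks} (list of \linkS4class{ImageStack}),
#'   \code{countsInSlab} (planted cells per section), \code{plantedTotal},
#'   \code{geometry}
#' @export
generateSerialSections <- function(geometry, nTotalCells, nSections = 6,
                                   pixelSize = 2,
                                   cellDiameterRange = c(12, 20),
                                   cellIntensity = 200, noiseSd = 8,
                                   zSpanFraction = 0.6, seed = 1L) {
  validObject(geometry)
  stopifnot(nTotalCells > 0, nSections >= 1)
  withSeed(seed, {
    aX <- geometry@length / 2 * 1000  # um, column direction
    aY <- geometry@width / 2 * 1000   # um, row direction
    aZ <- geometry@depth / 2 * 1000
    thick <- geometry@sectionThickness
    ## uniform points in the ellipsoid by batch rejection
    pts <- matrix(numeric(0), 0, 3)
    while (nrow(pts) < nTotalCells) {
      m <- ceiling((nTotalCells - nrow(pts)) / 0.5)
      cand <- cbind(stats::runif(m, -aX, aX), stats::runif(m, -aY, aY),
                    stats::runif(m, -aZ, aZ))
      keep <- (cand[, 1] / aX)^2 + (cand[, 2] / aY)^2 + (cand[, 3] / aZ)^2 <= 1
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(nTotalCells), , drop = FALSE]
    diam <- stats::runif(nTotalCells, cellDiameterRange[1],
                         cellDiameterRange[2])
    zs <- seq(-zSpanFraction * aZ, zSpanFraction * aZ, length.out = nSections)
    ps <- pixelSize
    nr <- ceiling(2 * aY / ps) + 40L
    nc <- ceiling(2 * aX / ps) + 40L
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    rowsN <- (1:nr - cy) * ps  # um offsets of pixel centres
    colsN <- (1:nc - cx) * ps
    stacks <- vector("list", nSections)
    countsInSlab <- integer(nSections)
    for (s in seq_len(nSections)) {
      z <- zs[s]
      scale <- sqrt(max(0, 1 - (z / aZ)^2))
      ellipse <- outer((rowsN / (aY * scale))^2, (colsN / (aX * scale))^2,
                       "+") <= 1
      inSlab <- abs(pts[, 3] - z) <= thick / 2
      countsInSlab[s] <- sum(inSlab)
      nuclei <- ellipse * 120
      reporter <- matrix(0, nr, nc)
      for (i in which(inSlab)) {
        r0 <- cy + pts[i, 2] / ps
        c0 <- cx + pts[i, 1] / ps
        reporter[diskIndices(r0, c0, (diam[i] / 2) / ps, nr, nc)] <-
          cellIntensity
      }
      if (noiseSd > 0) {
        nuclei <- nuclei + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
        reporter <- reporter + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
      }
      stacks[[s]] <- new("ImageStack",
                         channels = list(nuclei = clamp8bit(nuclei),
                                         reporter = clamp8bit(reporter)),
                         pixelSize = ps, bitDepth = 8L)
    }
    list(stacks = stacks, countsInSlab = countsInSlab,
         plantedTotal = nTotalCells, geometry = geometry)
  })
}
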