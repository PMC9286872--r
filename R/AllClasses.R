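#' @import methods
NULL

## Fixed renal compartment vocabulary, outermost first.
ZONE_NAMES <- c("cortex", "OSOM", "ISOM", "IM", "papilla")

#' Calibrated multi-channel section image
#'
#' Container for a 2D multi-channel fluorescence section. Channels are named
#' intensity matrices sharing one shape; recognised roles are \code{nuclei}
#' (DAPI), \code{autofluorescence} (green tubular signal), \code{reporter}
#' (tdTomato), \code{marker} (immunofluorescence) and \code{fish}. Pixel size
#' carries the physical calibration in micrometres per pixel.
#'
#' @slot channels named list of numeric matrices, all with identical dimensions
#' @slot pixelSize micrometres per pixel (> 0)
#' @slot bitDepth bit depth of the source data (e.g. 8L, 16L)
#' @exportClass ImageStack
setClass("ImageStack",
  representation(channels = "list", pixelSize = "numeric", bitDepth = "integer"),
  prototype(channels = list(), pixelSize = 1, bitDepth = 8L))

setValidity("ImageStack", function(object) {
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@channels) == 0L)
    return("at least one channel is required")
  if (is.null(names(object@channels)) || any(!nzchar(names(object@channels))))
    return("channels must be named")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    return("all channels must be matrices")
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, ref), logical(1))))
    return("all channels must share one shape")
  TRUE
})

#' Detection stage parameters
#'
#' @slot minDiameter minimum equivalent-circle diameter in micrometres for a
#'   connected component to be counted as a cell (default 10, inclusive cutoff)
#' @slot backgroundRadius half-width of the median background filter in
#'   micrometres (default 50)
#' @slot connectivity pixel connectivity for component labeling, 4 or 8
#' @slot gaussianSigma Gaussian smoothing sigma in micrometres for the tissue
#'   mask (default 10)
#' @slot closeRadius morphological closing disk radius in micrometres for the
#'   tissue mask (default 20)
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(minDiameter = "numeric", backgroundRadius = "numeric",
    connectivity = "integer", gaussianSigma = "numeric", closeRadius = "numeric"),
  prototype(minDiameter = 10, backgroundRadius = 50, connectivity = 8L,
    gaussianSigma = 10, closeRadius = 20))

setValidity("DetectionParams", function(object) {
  if (object@minDiameter <= 0) return("minDiameter must be > 0")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (object@backgroundRadius <= 0) return("backgroundRadius must be > 0")
  if (object@gaussianSigma <= 0) return("gaussianSigma must be > 0")
  if (object@closeRadius <= 0) return("closeRadius must be > 0")
  TRUE
})

#' Set of detected reporter cells
#'
#' One row of \code{table} per detected cell: \code{id}, 0-based centroid pixel
#' indices \code{row_px}/\code{col_px}, physical centroid \code{x_um} (column
#' direction) and \code{y_um} (row direction), \code{area_um2}, equivalent
#' circle diameter \code{eq_diameter_um}, \code{zone} (compartment label or
#' \code{"unassigned"}, NA before zone assignment) and \code{marker_positive}
#' (NA before double-positive calling). \code{pixels} keeps each component's
#' linear pixel indices so pixel-overlap operations act on the true component
#' shape.
#'
#' @slot table data.frame of per-cell measurements
#' @slot pixels list of integer vectors (column-major linear pixel indices)
#' @slot dim image dimensions the pixel indices refer to
#' @slot pixelSize micrometres per pixel
#' @slot noSignal TRUE when thresholding found no separable signal (empty set
#'   returned with this warning flag rather than an error)
#' @exportClass CellDetections
setClass("CellDetections",
  representation(table = "data.frame", pixels = "list", dim = "integer",
    pixelSize = "numeric", noSignal = "logical"),
  prototype(table = data.frame(), pixels = list(), dim = c(0L, 0L),
    pixelSize = 1, noSignal = FALSE))

setValidity("CellDetections", function(object) {
  if (nrow(object@table) != length(object@pixels))
    return("one pixel set per detection required")
  if (nrow(object@table) > 0) {
    need <- c("id", "row_px", "col_px", "x_um", "y_um", "area_um2",
              "eq_diameter_um", "zone", "marker_positive")
    if (!all(need %in% names(object@table)))
      return(paste("table must contain:", paste(need, collapse = ", ")))
  }
  TRUE
})

#' Tissue mask from the nuclei channel
#'
#' @slot mask logical matrix, TRUE on tissue
#' @slot pixelSize micrometres per pixel
#' @slot empty TRUE when no foreground was found (area 0, warning flag)
#' @exportClass TissueMask
setClass("TissueMask",
  representation(mask = "matrix", pixelSize = "numeric", empty = "logical"),
  prototype(mask = matrix(FALSE, 0, 0), pixelSize = 1, empty = FALSE))

#' Renal compartment label image
#'
#' Integer label image over the fixed vocabulary: 0 = background, 1 = cortex,
#' 2 = OSOM, 3 = ISOM, 4 = IM, 5 = papilla (outermost first). Zone maps are
#' inputs to the analysis (curated label images, or the synthetic generator's
#' concentric elliptical banding); they are never computed from the data.
#'
#' @slot labels integer matrix with values in 0..5
#' @slot pixelSize micrometres per pixel
#' @exportClass ZoneMap
setClass("ZoneMap",
  representation(labels = "matrix", pixelSize = "numeric"),
  prototype(labels = matrix(0L, 0, 0), pixelSize = 1))

setValidity("ZoneMap", function(object) {
  if (!all(object@labels %in% 0:5))
    return("zone labels must be integers in 0..5")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' Kidney geometry for the ellipsoid extrapolation
#'
#' Maximum longitudinal diameter (length), width and depth of the kidney in
#' millimetres, plus the cryosection thickness in micrometres (default 12).
#'
#' @slot length mm
#' @slot width mm
#' @slot depth mm
#' @slot sectionThickness micrometres
#' @exportClass KidneyGeometry
setClass("KidneyGeometry",
  representation(length = "numeric", width = "numeric", depth = "numeric",
    sectionThickness = "numeric"),
  prototype(length = 12, width = 6, depth = 5, sectionThickness = 12))

setValidity("KidneyGeometry", function(object) {
  v <- c(object@length, object@width, object@depth, object@sectionThickness)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all geometry values must be positive")
  TRUE
})

#' Binarized immunofluorescence marker mask
#'
#' Marker thresholds are experiment-level configuration (selected once and
#' maintained), so the threshold used is recorded for provenance.
#'
#' @slot mask logical matrix
#' @slot threshold 8-bit grayscale threshold that produced the mask
#' @slot markerName marker channel name (e.g. "aSMA", "vimentin")
#' @exportClass MarkerMask
setClass("MarkerMask",
  representation(mask = "matrix", threshold = "numeric", markerName = "character"),
  prototype(mask = matrix(FALSE, 0, 0), threshold = 0, markerName = "marker"))

#' Clustered FISH transcript dots
#'
#' Result of single-linkage clustering of single-molecule FISH dots: each
#' cluster is interpreted as one cell of origin. \code{cells} has one row per
#' cluster (id, dot count, centroid, tagged flag, matched detection id);
#' \code{membership} maps each input dot to its cluster id.
#'
#' @slot cells data.frame: id, n_dots, x_um, y_um, tagged, detection_id
#' @slot dots the input dot table (x_um, y_um, ...)
#' @slot membership integer cluster id per dot
#' @slot clusterRadius linkage radius in micrometres
#' @exportClass FishCellSet
setClass("FishCellSet",
  representation(cells = "data.frame", dots = "data.frame",
    membership = "integer", clusterRadius = "numeric"),
  prototype(cells = data.frame(), dots = data.frame(), membership = integer(0),
    clusterRadius = 5))

setValidity("FishCellSet", function(object) {
  if (length(object@membership) != nrow(object@dots))
    return("one membership entry per dot required")
  if (nrow(object@dots) > 0 &&
      !setequal(unique(object@membership), object@cells$id))
    return("membership ids must match cluster ids")
  TRUE
})

#' Cumulative transcript-contribution curve
#'
#' Lorenz-type curve over per-cell transcript counts sorted in descending
#' order: cumulative fraction of cells against cumulative fraction of
#' transcripts. With a descending sort the transcript fraction dominates the
#' cell fraction pointwise, with equality iff all counts are equal.
#'
#' @slot counts per-cell counts sorted descending
#' @slot cellFraction cumulative cell fraction (ends at 1)
#' @slot transcriptFraction cumulative transcript fraction (ends at 1)
#' @exportClass ContributionCurve
setClass("ContributionCurve",
  representation(counts = "numeric", cellFraction = "numeric",
    transcriptFraction = "numeric"))

setValidity("ContributionCurve", function(object) {
  n <- length(object@counts)
  if (length(object@cellFraction) != n || length(object@transcriptFraction) != n)
    return("curve vectors must have equal length")
  if (n > 0) {
    if (is.unsorted(object@cellFraction) || is.unsorted(object@transcriptFraction))
      return("cumulative fractions must be monotone")
    if (abs(object@cellFraction[n] - 1) > 1e-9 ||
        abs(object@transcriptFraction[n] - 1) > 1e-9)
      return("cumulative fractions must end at 1")
  }
  TRUE
})

#' Linear carboxyhaemoglobin washout fit
#'
#' Ordinary least-squares line fitted to the above-baseline part of a CO-Hb
#' washout series. The half-life is defined on the above-baseline saturation
#' under the linear model: the time for S(t) - baseline to fall to half its
#' fitted t = 0 value, i.e. (S0 - baseline) / (2 |slope|).
#'
#' @slot slope %/min (negative for a valid washout)
#' @slot intercept fitted saturation at t = 0 (%)
#' @slot rSquared coefficient of determination of the fit
#' @slot halfLife minutes
#' @slot baseline baseline CO-Hb saturation used (%)
#' @slot nUsed number of above-baseline points entering the fit
#' @exportClass WashoutFit
setClass("WashoutFit",
  representation(slope = "numeric", intercept = "numeric", rSquared = "numeric",
    halfLife = "numeric", baseline = "numeric", nUsed = "integer"))

#' Synthetic kidney-section specification
#'
#' Parameters of the ground-truth generator. Defaults describe the study
#' conditions the pipeline is benchmarked under: a 1024x1024 frame at
#' 2 um/px, an elliptical tissue with concentric zone bands (outermost =
#' cortex), 300 reporter cells concentrated at the corticomedullary border,
#' 12-20 um cell diameters at intensity 200 over Gaussian noise of SD 8
#' (signal >= 5x noise), and burst-like per-cell FISH counts from a negative
#' binomial with mean 5 and dispersion size 1.636 (top decile of cells carries
#' ~30% of transcripts).
#'
#' @slot imageShape image dimensions in pixels (rows, cols)
#' @slot pixelSize micrometres per pixel
#' @slot zoneBandFractions 5 radial-width fractions (cortex, OSOM, ISOM, IM,
#'   papilla; outermost first) summing to 1
#' @slot nCellsPerZone planted reporter cells per zone
#' @slot cellDiameterRange cell diameter range in micrometres (low, high)
#' @slot cellIntensity 8-bit intensity of planted cells
#' @slot tubuleFraction fraction of tissue covered by autofluorescent tubules
#' @slot markerOverlapProb probability a planted cell is marker-positive
#' @slot markerExtraAreaFrac marker-positive tissue area outside cells
#' @slot fishCountMean mean of the per-cell transcript count distribution
#' @slot fishCountDispersion negative-binomial size parameter (smaller = more
#'   over-dispersed / burstier)
#' @slot dotJitterSd FISH dot scatter SD around the cell centroid (um)
#' @slot noiseSd Gaussian image noise SD in 8-bit levels
#' @slot seed integer seed; all generator randomness flows from it
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(imageShape = "integer", pixelSize = "numeric",
    zoneBandFractions = "numeric", nCellsPerZone = "integer",
    cellDiameterRange = "numeric", cellIntensity = "numeric",
    tubuleFraction = "numeric", markerOverlapProb = "numeric",
    markerExtraAreaFrac = "numeric", fishCountMean = "numeric",
    fishCountDispersion = "numeric", dotJitterSd = "numeric",
    noiseSd = "numeric", seed = "integer"),
  prototype(imageShape = c(1024L, 1024L), pixelSize = 2,
    zoneBandFractions = c(0.35, 0.15, 0.20, 0.20, 0.10),
    nCellsPerZone = c(45L, 120L, 75L, 40L, 20L),
    cellDiameterRange = c(12, 20), cellIntensity = 200,
    tubuleFraction = 0.3, markerOverlapProb = 0.25,
    markerExtraAreaFrac = 0.02, fishCountMean = 5,
    fishCountDispersion = 1.636, dotJitterSd = 1.5, noiseSd = 8, seed = 1L))

setValidity("SyntheticSpec", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    return("imageShape must be two integers >= 16")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@zoneBandFractions) != 5L)
    return("zoneBandFractions must have 5 entries (cortex..papilla)")
  if (any(object@zoneBandFractions < 0))
    return("zoneBandFractions must be non-negative")
  if (abs(sum(object@zoneBandFractions) - 1) > 1e-9)
    return("zoneBandFractions must sum to 1")
  if (length(object@nCellsPerZone) != 5L || any(object@nCellsPerZone < 0L))
    return("nCellsPerZone must be 5 non-negative integers")
  if (length(object@cellDiameterRange) != 2L ||
      any(object@cellDiameterRange <= 0) ||
      diff(object@cellDiameterRange) < 0)
    return("cellDiameterRange must be positive (low, high)")
  for (p in c(object@tubuleFraction, object@markerOverlapProb,
              object@markerExtraAreaFrac))
    if (p < 0 || p > 1) return("fractions/probabilities must lie in [0, 1]")
  if (object@fishCountMean <= 0 || object@fishCountDispersion <= 0)
    return("fish count distribution parameters must be positive")
  if (object@dotJitterSd < 0) return("dotJitterSd must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Ground truth of a synthetic section
#'
#' @slot cells data.frame of planted cells: id, row_px, col_px, x_um, y_um,
#'   diameter_um, zone, marker_positive, fish_count
#' @slot dots data.frame of planted FISH dots: x_um, y_um, cell_id
#' @slot zoneMap ZoneMap the cells were planted against
#' @slot tissueMask logical matrix of planted tissue
#' @slot tubuleMask logical matrix of autofluorescent tubules
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(cells = "data.frame", dots = "data.frame", zoneMap = "ZoneMap",
    tissueMask = "matrix", tubuleMask = "matrix"),
  prototype(cells = data.frame(), dots = data.frame()))
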