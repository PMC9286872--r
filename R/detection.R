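#' Detection stage parameters
#'
#' Constructor for \linkS4class{DetectionParams}. The defaults are the
#' published whole-slice analysis settings: a 10 um minimum equivalent
#' diameter (inclusive) for a component to count as a cell, median background
#' estimation over a 50 um half-width, 8-connectivity, and a 10 um Gaussian /
#' 20 um closing radius for the tissue mask.
#'
#' @param minDiameter minimum equivalent-circle diameter, micrometres
#' @param backgroundRadius median background filter half-width, micrometres
#' @param connectivity 4 or 8
#' @param gaussianSigma tissue-mask smoothing sigma, micrometres
#' @param closeRadius tissue-mask closing disk radius, micrometres
#' @return a validated \linkS4class{DetectionParams}
#' @examples
#' detectionParams(minDiameter = 12)
#' @export
detectionParams <- function(minDiameter = 10, backgroundRadius = 50,
                            connectivity = 8L, gaussianSigma = 10,
                            closeRadius = 20) {
  new("DetectionParams", minDiameter = minDiameter,
      backgroundRadius = backgroundRadius,
      connectivity = as.integer(connectivity),
      gaussianSigma = gaussianSigma, closeRadius = closeRadius)
}

#' Convert an intensity channel to 8-bit
#'
#' Linear min-max rescale to [0, 255] with rounding half up. A constant
#' channel (degenerate rescale) maps to all zeros by convention.
#'
#' @param channel numeric intensity matrix
#' @return numeric matrix with integer values in 0..255
#' @examples
#' to8bit(matrix(0:65535, 256, 256))[1, 1:3]
#' @export
to8bit <- function(channel) {
  if (length(channel) == 0L) stop("channel is empty")
  lo <- min(channel); hi <- max(channel)
  if (hi == lo) return(matrix(0, nrow(channel), ncol(channel)))
  clamp8bit((channel - lo) / (hi - lo) * 255)
}

#' Otsu threshold of an 8-bit histogram
#'
#' Returns the grayscale level t in 0..254 maximizing the between-class
#' variance over the split {<= t, > t}; foreground is defined as pixels
#' strictly above t. Ties are broken towards the smallest maximizing level.
#'
#' @param x either a 256-bin histogram of counts (levels 0..255) or an 8-bit
#'   intensity matrix, from which the histogram is taken
#' @return integer threshold level
#' @examples
#' h <- numeric(256); h[c(11, 201)] <- 100  # spikes at levels 10 and 200
#' otsuThreshold(h)
#' @export
otsuThreshold <- function(x) {
  if (is.matrix(x)) {
    v <- clamp8bit(x)
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  } else {
    if (length(x) != 256L) stop("histogram must have 256 bins (levels 0..255)")
    counts <- as.numeric(x)
  }
  if (any(counts < 0)) stop("negative histogram counts")
  if (sum(counts > 0) < 2L)
    stop(errorCondition("no separable classes: fewer than two populated bins",
                        class = "repquant_no_separable_classes"))
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)[1:255] / n            # weight of class {<= t}, t = 0..254
  m0 <- cumsum(counts * levels)[1:255] / n   # unnormalized class mean
  muT <- sum(counts * levels) / n
  valid <- w0 > 0 & w0 < 1
  sigmaB <- rep(-Inf, 255)
  sigmaB[valid] <- (muT * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  best <- max(sigmaB)
  tol <- 1e-9 * max(1, abs(best))
  as.integer(which(sigmaB >= best - tol)[1] - 1L)
}

#' Median background subtraction
#'
#' Estimates the large-scale background of an 8-bit channel with a median
#' filter of half-width \code{backgroundRadius} (converted to pixels) and
#' subtracts it, clipping at 0. Flattens slowly varying background while
#' leaving cell-scale bright structure intact.
#'
#' @param channel 8-bit intensity matrix (values 0..255)
#' @param backgroundRadius filter half-width in micrometres
#' @param pixelSize micrometres per pixel
#' @return background-subtracted 8-bit matrix
#' @export
subtractBackground <- function(channel, backgroundRadius = 50, pixelSize = 1) {
  radiusPx <- round(backgroundRadius / pixelSize)
  if (radiusPx < 3)
    stop("backgroundRadius must be at least 3 pixels (got ", radiusPx, " px)")
  # the median filter window cannot exceed the frame
  radiusPx <- min(radiusPx, (min(dim(channel)) - 1L) %/% 2L)
  bg <- EBImage::imageData(EBImage::medianFilter(channel / 255, radiusPx)) * 255
  pmax(channel - floor(bg + 0.5), 0)
}

#' Detect reporter-positive cells
#'
#' The whole-slice counting pipeline: 8-bit conversion, median background
#' subtraction, Otsu binarization (foreground strictly above threshold),
#' connected-component labeling, and removal of components whose
#' equivalent-circle diameter (2 sqrt(area / pi), from the component area in
#' um^2) is below \code{minDiameter} (inclusive cutoff: components exactly at
#' the cutoff are kept). Components touching the image border are kept, and
#' touching cells are counted as single components. When thresholding finds no
#' separable signal (e.g. a blank frame) an empty set is returned with the
#' \code{noSignal} flag raised and a warning, not an error.
#'
#' @param reporter an \linkS4class{ImageStack} (its \code{reporter} channel is
#'   used) or a numeric intensity matrix
#' @param pixelSize micrometres per pixel; taken from the stack when
#'   \code{reporter} is an \linkS4class{ImageStack}
#' @param params a \linkS4class{DetectionParams}
#' @return a \linkS4class{CellDetections}, sorted by centroid (row, col)
#' @examples
#' sim <- generateSection(syntheticSpec(seed = 7))
#' det <- detectCells(sim$image)
#' nCells(det)
#' @export
detectCells <- function(reporter, pixelSize = NULL, params = detectionParams()) {
  if (is(reporter, "ImageStack")) {
    pixelSize <- reporter@pixelSize
    reporter <- getChannel(reporter, "reporter")
  }
  if (is.null(pixelSize)) stop("pixelSize is required for a plain matrix")
  validObject(params)
  ps <- pixelSize
  x <- to8bit(reporter)
  x <- subtractBackground(x, params@backgroundRadius, ps)
  emptySet <- function() {
    warning("no detectable signal: threshold degenerate, returning 0 detections")
    new("CellDetections", table = emptyDetectionTable(), pixels = list(),
        dim = dim(reporter), pixelSize = ps, noSignal = TRUE)
  }
  thr <- tryCatch(otsuThreshold(x), repquant_no_separable_classes = function(e) NULL)
  if (is.null(thr)) return(emptySet())
  mask <- x > thr
  comps <- componentPixelSets(mask, params@connectivity)
  nr <- nrow(reporter)
  rows <- lapply(comps, function(px) ((px - 1L) %% nr) + 1L)
  cols <- lapply(comps, function(px) ((px - 1L) %/% nr) + 1L)
  areaUm2 <- vapply(comps, length, integer(1)) * ps^2
  eqd <- 2 * sqrt(areaUm2 / pi)
  keep <- eqd >= params@minDiameter
  comps <- comps[keep]; rows <- rows[keep]; cols <- cols[keep]
  areaUm2 <- areaUm2[keep]; eqd <- eqd[keep]
  if (length(comps) == 0L)
    return(new("CellDetections", table = emptyDetectionTable(),
               pixels = list(), dim = dim(reporter), pixelSize = ps,
               noSignal = FALSE))
  cr <- vapply(rows, mean, numeric(1)) - 1   # 0-based fractional centroids
  cc <- vapply(cols, mean, numeric(1)) - 1
  ord <- order(cr, cc)
  tab <- data.frame(id = seq_along(ord), row_px = cr[ord], col_px = cc[ord],
                    x_um = cc[ord] * ps, y_um = cr[ord] * ps,
                    area_um2 = areaUm2[ord], eq_diameter_um = eqd[ord],
                    zone = NA_character_, marker_positive = NA)
  new("CellDetections", table = tab, pixels = comps[ord], dim = dim(reporter),
      pixelSize = ps, noSignal = FALSE)
}

emptyDetectionTable <- function() {
  data.frame(id = integer(0), row_px = numeric(0), col_px = numeric(0),
             x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
             eq_diameter_um = numeric(0), zone = character(0),
             marker_positive = logical(0))
}

#' Tissue mask from the DAPI channel
#'
#' Determines the tissue (kidney) area from nuclear fluorescence: Gaussian
#' smoothing, Otsu binarization, morphological closing with a disk to merge
#' the region, retention of the largest connected component, and hole filling.
#' Area is reported in mm^2 via \code{\link{maskArea}}.
#'
#' @param nuclei an \linkS4class{ImageStack} (its \code{nuclei} channel is
#'   used) or a numeric intensity matrix
#' @param pixelSize micrometres per pixel (for a plain matrix)
#' @param params a \linkS4class{DetectionParams}
#' @return a \linkS4class{TissueMask}; empty foreground yields a zero-area
#'   mask with the \code{empty} flag raised and a warning
#' @export
computeTissueMask <- function(nuclei, pixelSize = NULL,
                              params = detectionParams()) {
  if (is(nuclei, "ImageStack")) {
    pixelSize <- nuclei@pixelSize
    nuclei <- getChannel(nuclei, "nuclei")
  }
  if (is.null(pixelSize)) stop("pixelSize is required for a plain matrix")
  validObject(params)
  ps <- pixelSize
  x <- to8bit(nuclei)
  sm <- EBImage::imageData(EBImage::gblur(x, sigma = params@gaussianSigma / ps))
  emptyMask <- function() {
    warning("empty tissue foreground: zero-area mask returned")
    new("TissueMask", mask = matrix(FALSE, nrow(nuclei), ncol(nuclei)),
        pixelSize = ps, empty = TRUE)
  }
  thr <- tryCatch(otsuThreshold(clamp8bit(sm)),
                  repquant_no_separable_classes = function(e) NULL)
  if (is.null(thr)) return(emptyMask())
  mask <- sm > thr
  if (!any(mask)) return(emptyMask())
  brushSize <- 2L * as.integer(round(params@closeRadius / ps)) + 1L
  closed <- EBImage::imageData(
    EBImage::closing(mask * 1, EBImage::makeBrush(brushSize, "disc"))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(closed * 1))
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  filled <- EBImage::imageData(EBImage::fillHull((lab == biggest) * 1)) > 0
  new("TissueMask", mask = filled, pixelSize = ps, empty = FALSE)
}
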