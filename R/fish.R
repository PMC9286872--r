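#' Detect FISH dots in a fluorescence channel
#'
#' Simple automated blob detector for synthetic end-to-end runs: Gaussian
#' smoothing at the dot scale, Otsu binarization, connected components, and
#' intensity-weighted (sub-pixel) centroids converted to micrometres. The
#' canonical input for transcript quantification remains a manually annotated
#' dot table; this detector exists so synthetic pipelines need no manual step.
#' Dots closer than the detector's resolution (about one pixel) merge into
#' one: a documented limitation, flagged through the \code{source} attribute.
#'
#' @param channel FISH intensity matrix, or an \linkS4class{ImageStack} (its
#'   \code{fish} channel is used)
#' @param pixelSize micrometres per pixel (for a plain matrix)
#' @param smoothSigmaUm Gaussian smoothing sigma in micrometres
#' @return data.frame(x_um, y_um, channel) with attribute
#'   \code{source = "detector"}; empty for a blank channel
#' @export
detectDots <- function(channel, pixelSize = NULL, smoothSigmaUm = 1) {
  if (is(channel, "ImageStack")) {
    pixelSize <- channel@pixelSize
    channel <- getChannel(channel, "fish")
  }
  if (is.null(pixelSize)) stop("pixelSize is required for a plain matrix")
  ps <- pixelSize
  x <- to8bit(channel)
  sm <- EBImage::imageData(EBImage::gblur(x, sigma = max(smoothSigmaUm / ps,
                                                         0.3)))
  empty <- function() {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      channel = character(0))
    attr(out, "source") <- "detector"
    out
  }
  thr <- tryCatch(otsuThreshold(clamp8bit(sm)),
                  repquant_no_separable_classes = function(e) NULL)
  if (is.null(thr)) return(empty())
  mask <- sm > thr
  comps <- componentPixelSets(mask, 8L)
  if (length(comps) == 0L) return(empty())
  nr <- nrow(channel)
  cent <- t(vapply(comps, function(px) {
    r <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    w <- sm[px]
    c(sum(r * w) / sum(w), sum(cc * w) / sum(w))
  }, numeric(2)))
  out <- data.frame(x_um = (cent[, 2] - 1) * ps, y_um = (cent[, 1] - 1) * ps,
                    channel = rep("fish", nrow(cent)))
  attr(out, "source") <- "detector"
  out
}

#' Cluster FISH dots into cells of origin
#'
#' Single-linkage clustering with an inclusive radius: dots i and j belong to
#' one cluster iff they are connected by a chain of pairwise Euclidean
#' distances <= \code{clusterRadius}. Dots forming clusters within 5 um (the
#' default) are considered to originate from the same cell; each cluster's
#' transcript count is its dot count and its centroid the mean of its
#' members.
#'
#' @param dots data.frame with columns \code{x_um}, \code{y_um} (one row per
#'   dot)
#' @param clusterRadius linkage radius in micrometres (> 0)
#' @return a \linkS4class{FishCellSet}; clusters (cells) are ordered by
#'   centroid (y, x)
#' @examples
#' d <- data.frame(x_um = c(0, 0, 0), y_um = c(0, 4, 9))
#' nCells(clusterDots(d))  # one cluster: chain 0-4-9 with links 4 and 5 um
#' @export
clusterDots <- function(dots, clusterRadius = 5) {
  if (clusterRadius <= 0) stop("clusterRadius must be > 0")
  n <- nrow(dots)
  emptyCells <- data.frame(id = integer(0), n_dots = integer(0),
                           x_um = numeric(0), y_um = numeric(0),
                           tagged = logical(0), detection_id = integer(0))
  if (is.null(n) || n == 0L)
    return(new("FishCellSet",
               cells = emptyCells,
               dots = data.frame(x_um = numeric(0), y_um = numeric(0)),
               membership = integer(0), clusterRadius = clusterRadius))
  xy <- cbind(dots$x_um, dots$y_um)
  if (n == 1L) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(xy), method = "single")
    memb <- stats::cutree(hc, h = clusterRadius)
  }
  sums <- rowsum(xy, memb)                       # rows ordered by cluster id
  sizes <- as.integer(rowsum(rep(1, n), memb))
  cx <- sums[, 1] / sizes
  cy <- sums[, 2] / sizes
  ord <- order(cy, cx)
  newId <- integer(length(ord)); newId[ord] <- seq_along(ord)
  cells <- data.frame(id = seq_along(ord), n_dots = sizes[ord],
                      x_um = cx[ord], y_um = cy[ord],
                      tagged = NA, detection_id = NA_integer_)
  new("FishCellSet", cells = cells, dots = as.data.frame(dots),
      membership = as.integer(newId[memb]), clusterRadius = clusterRadius)
}

#' Co-label FISH cells with tagged reporter detections
#'
#' A FISH cell is tagged iff its centroid lies inside a detection's component
#' pixel set; failing that, iff it lies within \code{matchRadius} of a
#' detection centroid. This containment-then-radius rule mirrors visual
#' double-positive counting of transcript clusters on reporter-stained
#' sections. The matched detection id is recorded per FISH cell.
#'
#' @param fishCells a \linkS4class{FishCellSet}
#' @param detections a \linkS4class{CellDetections} in the same coordinate
#'   frame (micrometres)
#' @param matchRadius fallback matching radius, micrometres
#' @return the \linkS4class{FishCellSet} with \code{tagged} and
#'   \code{detection_id} filled
#' @export
tagFishCells <- function(fishCells, detections, matchRadius = 5) {
  stopifnot(is(fishCells, "FishCellSet"), is(detections, "CellDetections"))
  cells <- fishCells@cells
  if (nrow(cells) == 0L) return(fishCells)
  ps <- detections@pixelSize
  if (!is.finite(ps) || ps <= 0) stop("detections carry no valid calibration")
  nr <- detections@dim[1]; nc <- detections@dim[2]
  dtab <- detections@table
  ## label image of detection components for the containment test
  lab <- NULL
  if (nCells(detections) > 0 && nr > 0) {
    lab <- matrix(0L, nr, nc)
    for (i in seq_along(detections@pixels))
      lab[detections@pixels[[i]]] <- dtab$id[i]
  }
  tagged <- logical(nrow(cells))
  matched <- rep(NA_integer_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- round(cells$y_um[i] / ps) + 1L
    cc <- round(cells$x_um[i] / ps) + 1L
    if (!is.null(lab) && r >= 1L && r <= nr && cc >= 1L && cc <= nc &&
        lab[r, cc] > 0L) {
      tagged[i] <- TRUE
      matched[i] <- lab[r, cc]
    } else if (nCells(detections) > 0) {
      d <- sqrt((dtab$x_um - cells$x_um[i])^2 + (dtab$y_um - cells$y_um[i])^2)
      j <- which.min(d)
      if (d[j] <= matchRadius) {
        tagged[i] <- TRUE
        matched[i] <- dtab$id[j]
      }
    }
  }
  cells$tagged <- tagged
  cells$detection_id <- matched
  fishCells@cells <- cells
  fishCells
}

#' Two-way composition percentages of FISH and reporter cells
#'
#' Reports (a) the percent of tagged reporter detections that are
#' FISH-positive (matched by at least one FISH cell) and (b) the percent of
#' FISH cells that are tagged, with numerators and denominators for
#' auditability. A zero denominator yields an NA percentage with the
#' corresponding \code{*_defined} flag set to FALSE, never a fabricated 0.
#'
#' @param fishCells a tagged \linkS4class{FishCellSet} (see
#'   \code{\link{tagFishCells}})
#' @param detections the \linkS4class{CellDetections} used for tagging
#' @return list: pct_tagged_fish_positive, pct_fish_tagged, n_tagged_cells,
#'   n_fish_positive_tagged, n_fish_cells, n_fish_tagged, and *_defined flags
#' @export
compositionStats <- function(fishCells, detections) {
  stopifnot(is(fishCells, "FishCellSet"), is(detections, "CellDetections"))
  cells <- fishCells@cells
  if (nrow(cells) > 0 && anyNA(cells$tagged))
    stop("run tagFishCells first")
  nDet <- nCells(detections)
  fishPosDet <- length(unique(cells$detection_id[!is.na(cells$detection_id)]))
  nFish <- nrow(cells)
  nFishTagged <- sum(cells$tagged)
  list(
    pct_tagged_fish_positive = if (nDet > 0) 100 * fishPosDet / nDet
                               else NA_real_,
    tagged_fish_positive_defined = nDet > 0,
    pct_fish_tagged = if (nFish > 0) 100 * nFishTagged / nFish else NA_real_,
    fish_tagged_defined = nFish > 0,
    n_tagged_cells = nDet, n_fish_positive_tagged = fishPosDet,
    n_fish_cells = nFish, n_fish_tagged = nFishTagged)
}

#' Cumulative transcript-contribution curve
#'
#' Sorts per-cell transcript counts in descending order and accumulates the
#' fraction of cells against the fraction of total transcripts (a Lorenz-type
#' curve read from the top): the curve exposes how a minority of
#' high-contributor cells carries a disproportionate transcript share under
#' burst-like expression.
#'
#' @param counts non-negative per-cell transcript counts, at least one
#'   positive
#' @return a \linkS4class{ContributionCurve}
#' @examples
#' cc <- contributionCurve(c(10, 1, 1, 1, 1))
#' contributorSlices(cc, 0.2)  # top 20% of cells carry 10/14 of transcripts
#' @export
contributionCurve <- function(counts) {
  if (length(counts) == 0L) stop("no counts given")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts are zero: no transcripts to apportion")
  s <- sort(counts, decreasing = TRUE)
  n <- length(s)
  new("ContributionCurve", counts = as.numeric(s),
      cellFraction = seq_len(n) / n,
      transcriptFraction = cumsum(s) / sum(s))
}

#' Transcript share of top cell fractions
#'
#' For each cell-fraction cutoff, the cumulative transcript share carried by
#' that top fraction of cells, read off the contribution curve with linear
#' interpolation between cell ranks (which also resolves ties at the cutoff
#' rank).
#'
#' @param curve a \linkS4class{ContributionCurve}
#' @param cellFractionCutoffs strictly increasing cutoffs in (0, 1]
#' @return numeric vector of transcript shares, one per cutoff
#' @export
contributorSlices <- function(curve, cellFractionCutoffs) {
  stopifnot(is(curve, "ContributionCurve"))
  co <- cellFractionCutoffs
  if (length(co) == 0L) stop("no cutoffs given")
  if (any(co <= 0 | co > 1)) stop("cutoffs must lie in (0, 1]")
  if (is.unsorted(co, strictly = TRUE)) stop("cutoffs must strictly increase")
  stats::approx(c(0, curve@cellFraction), c(0, curve@transcriptFraction),
                xout = co, ties = "ordered")$y
}
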