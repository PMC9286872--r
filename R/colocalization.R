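#' Binarize an immunofluorescence marker channel
#'
#' Applies the experiment-level fixed grayscale threshold after 8-bit
#' conversion: mask = channel > threshold. Marker thresholds are deliberate
#' configuration ("selected and maintained throughout the experiment"), never
#' auto-derived, and the value used is recorded for provenance.
#'
#' @param channel marker intensity matrix, or an \linkS4class{ImageStack}
#'   (its \code{marker} channel is used)
#' @param threshold 8-bit grayscale level in 0..255
#' @param markerName marker label for reports
#' @return a \linkS4class{MarkerMask}
#' @export
markerMask <- function(channel, threshold, markerName = "marker") {
  if (is(channel, "ImageStack")) channel <- getChannel(channel, "marker")
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  new("MarkerMask", mask = to8bit(channel) > threshold,
      threshold = threshold, markerName = markerName)
}

#' Marker-positive fraction of the tissue area
#'
#' |mask AND tissue| / |tissue|, in [0, 1].
#'
#' @param mask a \linkS4class{MarkerMask}
#' @param tissue a \linkS4class{TissueMask}
#' @return positive-area fraction
#' @export
positiveAreaFraction <- function(mask, tissue) {
  stopifnot(is(mask, "MarkerMask"), is(tissue, "TissueMask"))
  if (!identical(dim(mask@mask), dim(tissue@mask)))
    stop("marker and tissue mask shapes differ")
  denom <- sum(tissue@mask)
  if (denom == 0) stop("empty tissue mask")
  sum(mask@mask & tissue@mask) / denom
}

#' Call marker/reporter double-positive cells by pixel overlap
#'
#' A detection is double-positive iff its component pixel set overlaps the
#' marker mask by at least \code{minOverlapPx} pixels (default 10, inclusive:
#' exactly 10 overlapping pixels is positive). The rule is kept in pixels, as
#' defined; the recorded pixel size gives it physical meaning in reports.
#'
#' @param detections a \linkS4class{CellDetections}
#' @param mask a \linkS4class{MarkerMask} over the same image
#' @param minOverlapPx minimum overlapping pixel count (>= 1)
#' @return the \linkS4class{CellDetections} with \code{marker_positive}
#'   filled, plus attributes on its table are left untouched; the summary is
#'   attached as attribute \code{summary} of the returned object's table:
#'   list(marker, threshold, n_cells, n_double_positive, percent)
#' @export
callDoublePositives <- function(detections, mask, minOverlapPx = 10L) {
  stopifnot(is(detections, "CellDetections"), is(mask, "MarkerMask"))
  minOverlapPx <- as.integer(minOverlapPx)
  if (minOverlapPx < 1L) stop("minOverlapPx must be >= 1")
  if (!identical(dim(mask@mask), detections@dim))
    stop("marker mask shape does not match detection image shape")
  ov <- vapply(detections@pixels, function(px) sum(mask@mask[px]), numeric(1))
  pos <- ov >= minOverlapPx
  tab <- detections@table
  tab$marker_positive <- as.logical(pos)
  n <- nrow(tab)
  attr(tab, "summary") <- list(
    marker = mask@markerName, threshold = mask@threshold,
    min_overlap_px = minOverlapPx, n_cells = n,
    n_double_positive = sum(pos),
    percent = if (n > 0) 100 * sum(pos) / n else NA_real_)
  detections@table <- tab
  detections
}

#' Double-positive summary of a called detection set
#'
#' @param detections a \linkS4class{CellDetections} returned by
#'   \code{\link{callDoublePositives}}
#' @return the summary list (marker, threshold, min_overlap_px, n_cells,
#'   n_double_positive, percent)
#' @export
doublePositiveSummary <- function(detections) {
  s <- attr(detections@table, "summary")
  if (is.null(s)) stop("run callDoublePositives first")
  s
}
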