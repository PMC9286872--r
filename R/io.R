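## TIFF / CSV / JSON interfaces. Images travel as multi-page 8-bit TIFF (one
## page per channel); pixel size travels in the sidecar JSON config echo
## written next to each dataset.

#' Write an ImageStack as a multi-page TIFF
#'
#' One page per channel, 8-bit. Channel order is returned (and echoed into
#' dataset configs) because baseline TIFF pages carry no channel names.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output .tiff path
#' @return invisibly, the channel-name order written
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  pages <- lapply(stack@channels, function(ch) pmin(pmax(ch / 255, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(names(stack@channels))
}

#' Read a multi-page TIFF as an ImageStack
#'
#' @param path .tiff path
#' @param channelOrder channel role names, one per page
#' @param pixelSize micrometres per pixel (from the dataset config)
#' @return an \linkS4class{ImageStack}
#' @export
readImageStack <- function(path, channelOrder, pixelSize) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channelOrder))
    stop("TIFF has ", length(pages), " pages but ", length(channelOrder),
         " channel names were given")
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate grayscale-as-RGB
    floor(p * 255 + 0.5)
  })
  names(chans) <- channelOrder
  new("ImageStack", channels = chans, pixelSize = pixelSize, bitDepth = 8L)
}

#' Write a zone map as an indexed TIFF plus JSON legend
#'
#' Pixel values are the zone indices (0 = background, 1..5 = compartments);
#' the legend maps indices to compartment names.
#'
#' @param zones a \linkS4class{ZoneMap}
#' @param path output .tiff path; the legend goes to \code{<path>.legend.json}
#' @return invisibly, the legend list
#' @export
writeZoneMap <- function(zones, path) {
  stopifnot(is(zones, "ZoneMap"))
  tiff::writeTIFF(zones@labels / 255, path, bits.per.sample = 8L)
  legend <- c(list("0" = "background"),
              stats::setNames(as.list(ZONE_NAMES), as.character(1:5)))
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(legend)
}

#' Read an indexed zone map TIFF
#'
#' @param path .tiff path written by \code{\link{writeZoneMap}} (or any
#'   8-bit label TIFF with values 0..5)
#' @param pixelSize micrometres per pixel
#' @return a \linkS4class{ZoneMap}
#' @export
readZoneMap <- function(path, pixelSize) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  zoneMap(matrix(as.integer(floor(p * 255 + 0.5)), nrow(p), ncol(p)),
          pixelSize)
}

#' Write a detection table as CSV
#'
#' Columns: id, row_px, col_px, x_um, y_um, area_um2, eq_diameter_um, zone,
#' marker_positive.
#'
#' @param detections a \linkS4class{CellDetections}
#' @param path output .csv path
#' @return invisibly, the path
#' @export
writeDetectionsCsv <- function(detections, path) {
  stopifnot(is(detections, "CellDetections"))
  utils::write.csv(detections@table, path, row.names = FALSE)
  invisible(path)
}

#' Read a manually annotated FISH dot table
#'
#' The canonical transcript-quantification input: a CSV with columns
#' \code{x_um}, \code{y_um} and optionally \code{channel}, one row per
#' annotated fluorescent dot.
#'
#' @param path .csv path
#' @return data.frame with attribute \code{source = "manual"}
#' @export
readDotTable <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(d)))
    stop("dot table needs columns x_um, y_um")
  if (is.null(d$channel)) d$channel <- "fish"
  attr(d, "source") <- "manual"
  d
}
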