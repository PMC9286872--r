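#' Pixel size accessor
#' @param object an object carrying a physical calibration
#' @return micrometres per pixel
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "ZoneMap", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "TissueMask", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "CellDetections", function(object) object@pixelSize)

#' Channel access for an ImageStack
#' @param object an \linkS4class{ImageStack}
#' @return \code{channelNames}: character vector of channel roles
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname channelNames
setMethod("channelNames", "ImageStack", function(object) names(object@channels))

#' @rdname channelNames
#' @param name channel role to extract
#' @return \code{getChannel}: the named intensity matrix
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))
#' @rdname channelNames
setMethod("getChannel", "ImageStack", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no such channel: ", name, " (have: ",
         paste(names(object@channels), collapse = ", "), ")")
  object@channels[[name]]
})

#' Number of cells in a detection or FISH cell set
#' @param object a \linkS4class{CellDetections} or \linkS4class{FishCellSet}
#' @return integer count
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname nCells
setMethod("nCells", "CellDetections", function(object) nrow(object@table))
#' @rdname nCells
setMethod("nCells", "FishCellSet", function(object) nrow(object@cells))

#' Per-cell measurement table
#' @param object a \linkS4class{CellDetections} or \linkS4class{FishCellSet}
#' @return data.frame of per-cell rows
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname cellTable
setMethod("cellTable", "CellDetections", function(object) object@table)
#' @rdname cellTable
setMethod("cellTable", "FishCellSet", function(object) object@cells)

#' Mask area in square millimetres
#' @param object a \linkS4class{TissueMask}
#' @return area in mm^2: pixel count times (pixelSize/1000)^2
#' @export
setGeneric("maskArea", function(object) standardGeneric("maskArea"))
#' @rdname maskArea
setMethod("maskArea", "TissueMask", function(object)
  sum(object@mask) * (object@pixelSize / 1000)^2)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("ImageStack:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s) [",
      paste(names(object@channels), collapse = ", "), "],",
      object@pixelSize, "um/px\n")
})

setMethod("show", "CellDetections", function(object) {
  cat("CellDetections:", nrow(object@table), "cell(s),",
      object@pixelSize, "um/px")
  if (object@noSignal) cat("  [warning: no detectable signal]")
  cat("\n")
  if (nrow(object@table) > 0) {
    zoned <- sum(!is.na(object@table$zone))
    if (zoned > 0) cat("  zone-assigned:", zoned, "\n")
    mk <- sum(object@table$marker_positive, na.rm = TRUE)
    if (any(!is.na(object@table$marker_positive)))
      cat("  marker double-positive:", mk, "\n")
  }
})

setMethod("show", "TissueMask", function(object) {
  cat("TissueMask:", paste(dim(object@mask), collapse = " x "), "px, area",
      signif(maskArea(object), 5), "mm^2")
  if (object@empty) cat("  [warning: empty foreground]")
  cat("\n")
})

setMethod("show", "ZoneMap", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 6L)
  cat("ZoneMap:", paste(dim(object@labels), collapse = " x "), "px,",
      object@pixelSize, "um/px\n  zone pixels:",
      paste(sprintf("%s=%d", c("background", ZONE_NAMES), tab), collapse = ", "),
      "\n")
})

setMethod("show", "FishCellSet", function(object) {
  cat("FishCellSet:", nrow(object@cells), "cell(s) from", nrow(object@dots),
      "dot(s), cluster radius", object@clusterRadius, "um\n")
  if (nrow(object@cells) > 0 && any(!is.na(object@cells$tagged)))
    cat("  tagged:", sum(object@cells$tagged, na.rm = TRUE), "\n")
})

setMethod("show", "WashoutFit", function(object) {
  cat(sprintf(
    "WashoutFit: slope %.4f %%/min, S0 %.2f%%, baseline %.2f%%, R2 %.4f\n",
    object@slope, object@intercept, object@baseline, object@rSquared))
  cat(sprintf("  half-life %.2f min (n = %d points)\n",
              object@halfLife, object@nUsed))
})

setMethod("show", "KidneyGeometry", function(object) {
  cat(sprintf("KidneyGeometry: L %.2f x W %.2f x D %.2f mm, sections %.1f um\n",
              object@length, object@width, object@depth,
              object@sectionThickness))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", paste(object@imageShape, collapse = " x "), "px at",
      object@pixelSize, "um/px,", sum(object@nCellsPerZone),
      "cells, seed", object@seed, "\n")
})
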