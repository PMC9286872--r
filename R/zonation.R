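#' Kidney geometry
#'
#' Constructor for \linkS4class{KidneyGeometry}: length is the maximum
#' longitudinal diameter measured on central sections, width and depth come
#' from central transverse sections, all in millimetres; section thickness in
#' micrometres (cryosections, default 12).
#'
#' @param length,width,depth kidney axes, mm
#' @param sectionThickness cryosection thickness, micrometres
#' @return a validated \linkS4class{KidneyGeometry}
#' @examples
#' kidneyGeometry(12, 6, 5)
#' @export
kidneyGeometry <- function(length, width, depth, sectionThickness = 12) {
  new("KidneyGeometry", length = length, width = width, depth = depth,
      sectionThickness = sectionThickness)
}

#' Zone map from a label matrix
#'
#' @param labels integer matrix with 0 = background and 1..5 = cortex, OSOM,
#'   ISOM, IM, papilla (outermost first)
#' @param pixelSize micrometres per pixel
#' @return a validated \linkS4class{ZoneMap}
#' @export
zoneMap <- function(labels, pixelSize) {
  storage.mode(labels) <- "integer"
  new("ZoneMap", labels = labels, pixelSize = pixelSize)
}

#' Renal compartment names
#'
#' The fixed zone vocabulary, outermost first.
#' @return character vector of the five compartment names
#' @examples zoneNames()
#' @export
zoneNames <- function() ZONE_NAMES

#' Assign detections to renal compartments
#'
#' Each detection is labelled by the zone at its centroid pixel (point
#' counting; the component's other pixels play no role). Centroids falling on
#' background are labelled \code{"unassigned"}; they are excluded from
#' per-zone statistics but remain in the table so totals stay auditable.
#'
#' @param detections a \linkS4class{CellDetections}
#' @param zones a \linkS4class{ZoneMap} with the same shape as the analyzed
#'   image
#' @return the \linkS4class{CellDetections} with the \code{zone} column filled
#' @export
assignZones <- function(detections, zones) {
  stopifnot(is(detections, "CellDetections"), is(zones, "ZoneMap"))
  if (!identical(dim(zones@labels), detections@dim))
    stop("zone map shape ", paste(dim(zones@labels), collapse = "x"),
         " does not match image shape ",
         paste(detections@dim, collapse = "x"))
  tab <- detections@table
  if (nrow(tab) > 0) {
    r <- pmin(pmax(round(tab$row_px) + 1L, 1L), nrow(zones@labels))
    cc <- pmin(pmax(round(tab$col_px) + 1L, 1L), ncol(zones@labels))
    lab <- zones@labels[cbind(r, cc)]
    tab$zone <- ifelse(lab == 0L, "unassigned", ZONE_NAMES[pmax(lab, 1L)])
  }
  detections@table <- tab
  detections
}

#' Per-zone density and percentage report
#'
#' For each compartment: cell count, zone area (mm^2), areal density
#' (cells/mm^2) and percent of assigned cells. Percentages are over
#' zone-assigned cells only; unassigned detections are reported alongside.
#' Zones of zero area get an undefined (NA) density with
#' \code{density_defined = FALSE}, never a fabricated 0.
#'
#' @param detections a zone-assigned \linkS4class{CellDetections}
#' @param zones the \linkS4class{ZoneMap} used for assignment
#' @return data.frame with one row per zone (columns zone, n_cells, area_mm2,
#'   density_cells_mm2, density_defined, percent) and attributes
#'   \code{n_unassigned}, \code{whole_slice_density} (all detections over
#'   total zoned area) and \code{total_assigned}
#' @export
zoneDensityReport <- function(detections, zones) {
  stopifnot(is(detections, "CellDetections"), is(zones, "ZoneMap"))
  if (all(zones@labels == 0L)) stop("empty zone map")
  tab <- detections@table
  if (nrow(tab) > 0 && anyNA(tab$zone))
    stop("detections must be zone-assigned first (see assignZones)")
  pxArea <- (zones@pixelSize / 1000)^2
  areas <- tabulate(zones@labels[zones@labels > 0L], nbins = 5L) * pxArea
  counts <- vapply(ZONE_NAMES, function(z) sum(tab$zone == z), integer(1))
  totalAssigned <- sum(counts)
  percent <- if (totalAssigned > 0) 100 * counts / totalAssigned
             else rep(NA_real_, 5)
  defined <- areas > 0
  density <- ifelse(defined, counts / areas, NA_real_)
  out <- data.frame(zone = ZONE_NAMES, n_cells = counts, area_mm2 = areas,
                    density_cells_mm2 = density, density_defined = defined,
                    percent = percent, row.names = NULL)
  attr(out, "n_unassigned") <- sum(tab$zone == "unassigned")
  attr(out, "total_assigned") <- totalAssigned
  attr(out, "whole_slice_density") <- nrow(tab) / sum(areas)
  out
}

#' Kidney volume from the ellipsoid equation
#'
#' V = (pi/6) L W D, with the axes in millimetres.
#'
#' @param geometry a \linkS4class{KidneyGeometry}
#' @return volume in mm^3
#' @examples
#' ellipsoidVolume(kidneyGeometry(1, 1, 1))  # pi/6
#' @export
ellipsoidVolume <- function(geometry) {
  validObject(geometry)
  pi / 6 * geometry@length * geometry@width * geometry@depth
}

#' Extrapolate a section density to a whole-kidney cell total
#'
#' Converts an areal density from a 2D section to a volumetric density by
#' dividing by the section thickness, then multiplies by the ellipsoid kidney
#' volume. No over-projection (Abercrombie) correction is applied: cells
#' thicker than the section are over-counted, a documented bias of the
#' procedure.
#'
#' @param arealDensity cells per mm^2 on the section
#' @param geometry a \linkS4class{KidneyGeometry}
#' @return list: \code{total} (cells per kidney), \code{volumetricDensity}
#'   (cells/mm^3), \code{arealDensity}, \code{volume} (mm^3)
#' @examples
#' estimateTotalCells(10, kidneyGeometry(12.4, 8.8, 9.3))$total
#' @export
estimateTotalCells <- function(arealDensity, geometry) {
  validObject(geometry)
  if (arealDensity < 0) stop("arealDensity must be >= 0")
  thickMm <- geometry@sectionThickness / 1000
  if (thickMm <= 0) stop("section thickness must be positive")
  volDensity <- arealDensity / thickMm
  vol <- ellipsoidVolume(geometry)
  list(total = volDensity * vol, volumetricDensity = volDensity,
       arealDensity = arealDensity, volume = vol)
}
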