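# 60x60 map at 10 um/px: cortex band on top 20 rows, OSOM next 20,
# background at the bottom; areas are exact multiples of the pixel area.
fixtureZoneMap <- function() {
  lab <- matrix(0L, 60, 60)
  lab[1:20, ] <- 1L
  lab[21:40, ] <- 2L
  zoneMap(lab, pixelSize = 10)
}

# detections at chosen pixel centroids without running the image pipeline
fakeDetections <- function(rows, cols, ps, dm = c(60L, 60L)) {
  n <- length(rows)
  tab <- data.frame(id = seq_len(n), row_px = rows, col_px = cols,
                    x_um = cols * ps, y_um = rows * ps,
                    area_um2 = rep(200, n), eq_diameter_um = rep(16, n),
                    zone = NA_character_, marker_positive = NA)
  new("CellDetections", table = tab,
      pixels = replicate(n, integer(0), simplify = FALSE),
      dim = dm, pixelSize = ps, noSignal = FALSE)
}

test_that("zone assignment is a centroid-pixel lookup with unassigned fallback", {
  zm <- fixtureZoneMap()
  det <- fakeDetections(rows = c(5, 25, 50), cols = c(10, 10, 10), ps = 10)
  det <- assignZones(det, zm)
  expect_equal(cellTable(det)$zone, c("cortex", "OSOM", "unassigned"))
  rep <- zoneDensityReport(det, zm)
  expect_equal(attr(rep, "n_unassigned"), 1L)
  expect_equal(sum(rep$n_cells), 2L)            # unassigned excluded
  expect_equal(sum(rep$percent), 100)
})

test_that("mismatched zone-map shapes are rejected", {
  det <- fakeDetections(5, 5, ps = 10, dm = c(30L, 30L))
  expect_error(assignZones(det, fixtureZoneMap()), "shape")
})

test_that("densities and percentages follow count / area exactly", {
  zm <- fixtureZoneMap()   # cortex area: 1200 px * (0.01 mm)^2 = 0.12 mm2
  det <- assignZones(fakeDetections(rep(5, 10), seq(2, 38, 4), ps = 10), zm)
  rep <- zoneDensityReport(det, zm)
  expect_equal(rep$density_cells_mm2[rep$zone == "cortex"], 10 / 0.12)
  expect_equal(rep$percent[rep$zone == "cortex"], 100)
  expect_false(rep$density_defined[rep$zone == "papilla"])  # zero-area zone
  expect_true(is.na(rep$density_cells_mm2[rep$zone == "papilla"]))
})

test_that("equal counts in all zones give 20 percent each", {
  lab <- matrix(0L, 50, 50)
  for (z in 1:5) lab[, (10 * z - 9):(10 * z)] <- z
  zm <- zoneMap(lab, pixelSize = 10)
  det <- assignZones(fakeDetections(rep(25, 5), c(4, 14, 24, 34, 44), ps = 10,
                                    dm = c(50L, 50L)), zm)
  rep <- zoneDensityReport(det, zm)
  expect_equal(rep$percent, rep(20, 5))
})

test_that("planted per-zone counts are recovered exactly end to end", {
  spec <- syntheticSpec(imageShape = c(512L, 512L),
                        nCellsPerZone = c(20L, 60L, 40L, 10L, 5L), seed = 41L)
  sim <- generateSection(spec)
  det <- assignZones(detectCells(sim$image), sim$truth@zoneMap)
  rep <- zoneDensityReport(det, sim$truth@zoneMap)
  expect_equal(rep$n_cells, c(20L, 60L, 40L, 10L, 5L))
  expect_equal(sum(rep$percent), 100)
  # zone areas sum to the tissue area of the map
  expect_equal(sum(rep$area_mm2),
               sum(sim$truth@zoneMap@labels > 0) * (2 / 1000)^2)
})

test_that("ellipsoid volume matches the closed form and its scaling law", {
  expect_equal(ellipsoidVolume(kidneyGeometry(1, 1, 1)), pi / 6)
  expect_equal(ellipsoidVolume(kidneyGeometry(2, 1, 1)), pi / 3)
  g1 <- kidneyGeometry(1.3, 0.8, 0.5)
  g2 <- kidneyGeometry(2.6, 1.6, 1.0)
  expect_equal(ellipsoidVolume(g2) / ellipsoidVolume(g1), 8)
  expect_error(kidneyGeometry(-1, 1, 1), "positive")
})

test_that("section-to-kidney extrapolation follows the arithmetic chain", {
  # density 10 /mm2, 12 um sections, volume forced to 500 mm3
  g <- kidneyGeometry(1, 1, 500 * 6 / pi, sectionThickness = 12)
  est <- estimateTotalCells(10, g)
  expect_equal(est$volume, 500)
  expect_equal(est$total, 10 / 0.012 * 500, tolerance = 1e-12)
  expect_equal(estimateTotalCells(0, g)$total, 0)
  # linear in density and in volume
  expect_equal(estimateTotalCells(20, g)$total, 2 * est$total)
  g8 <- kidneyGeometry(2, 2, 2 * 500 * 6 / pi, sectionThickness = 12)
  expect_equal(estimateTotalCells(10, g8)$total, 8 * est$total)
  expect_error(estimateTotalCells(-1, g), ">= 0")
})
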