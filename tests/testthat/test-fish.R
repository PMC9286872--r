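test_that("chained dots merge into one cluster at the inclusive 5 um radius", {
  d <- data.frame(x_um = c(0, 0, 0), y_um = c(0, 4, 9))
  fc <- clusterDots(d, 5)
  expect_equal(nCells(fc), 1L)            # links of 4 and exactly 5 um chain
  expect_equal(cellTable(fc)$n_dots, 3L)
  grid <- expand.grid(x_um = seq(0, 30, 6), y_um = seq(0, 30, 6))
  expect_equal(nCells(clusterDots(grid, 5)), nrow(grid))  # all gaps 6 um
  empty <- clusterDots(data.frame(x_um = numeric(0), y_um = numeric(0)), 5)
  expect_equal(nCells(empty), 0L)
})

test_that("single-linkage clustering equals brute-force transitive closure", {
  withr::with_seed(101, {
    for (i in 1:30) {
      n <- sample(2:60, 1)
      scale <- sample(c(3, 8, 20), 1)    # from dense chains to sparse fields
      xy <- cbind(runif(n, 0, scale * sqrt(n)), runif(n, 0, scale * sqrt(n)))
      fc <- clusterDots(data.frame(x_um = xy[, 1], y_um = xy[, 2]), 5)
      expect_true(samePartition(fc@membership, bfsClusters(xy, 5)))
    }
  })
})

test_that("increasing the cluster radius never increases the cluster count", {
  withr::with_seed(7, xy <- data.frame(x_um = runif(80, 0, 100),
                                       y_um = runif(80, 0, 100)))
  ks <- vapply(c(1, 3, 5, 10, 25), function(r) nCells(clusterDots(xy, r)),
               integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("the dot detector recovers isolated planted dots to sub-pixel accuracy", {
  rows <- rep(seq(20, 180, 40), each = 4)
  cols <- rep(seq(25, 145, 40), times = 5)
  img <- diskImage(200, 170, rows, cols, diamPx = rep(4, 20), intensity = 220)
  dots <- detectDots(img, pixelSize = 1)
  expect_equal(nrow(dots), 20L)
  expect_equal(attr(dots, "source"), "detector")
  m <- repquant:::matchPoints(cbind(dots$x_um, dots$y_um),
                              cbind(cols - 1, rows - 1), maxDist = 1)
  expect_equal(m$nMatched, 20L)
  blank <- detectDots(matrix(0, 64, 64), pixelSize = 1)
  expect_equal(nrow(blank), 0L)
})

test_that("FISH cells are tagged by containment, then by centroid proximity", {
  # detection occupying a 10x10 block near the origin of a 100x100 um frame
  px <- as.vector(outer(5:14, (5:14 - 1) * 100L, "+"))
  tab <- data.frame(id = 1L, row_px = 9, col_px = 9, x_um = 9, y_um = 9,
                    area_um2 = 100, eq_diameter_um = 11.3,
                    zone = NA_character_, marker_positive = NA)
  det <- new("CellDetections", table = tab, pixels = list(px),
             dim = c(100L, 100L), pixelSize = 1, noSignal = FALSE)
  fc <- clusterDots(data.frame(x_um = c(7, 7, 60), y_um = c(7, 8, 60)), 5)
  fc <- tagFishCells(fc, det)
  tabf <- cellTable(fc)
  inside <- which.min(tabf$x_um)
  expect_true(tabf$tagged[inside])                 # centroid inside component
  expect_equal(tabf$detection_id[inside], 1L)
  expect_false(tabf$tagged[which.max(tabf$x_um)])  # ~70 um away
})

test_that("co-placed FISH cells recover the planted tagging rate", {
  spec <- syntheticSpec(imageShape = c(768L, 768L),
                        nCellsPerZone = c(30L, 80L, 50L, 25L, 15L), seed = 43L)
  sim <- generateSection(spec)
  det <- detectCells(sim$image)
  cells <- sim$truth@cells
  withr::with_seed(44, {
    onCell <- runif(nrow(cells)) < 0.3
    # FISH cells: one 3-dot cluster on each chosen reporter cell, plus
    # far-away clusters on empty interstitium
    mk <- function(cx, cy) data.frame(x_um = cx + c(-1, 0, 1), y_um = cy)
    dotsOn <- do.call(rbind, Map(mk, cells$x_um[onCell], cells$y_um[onCell]))
  })
  fc <- tagFishCells(clusterDots(dotsOn, 5), det)
  frac <- mean(cellTable(fc)$tagged)
  se <- sqrt(0.3 * 0.7 / nrow(cells))
  expect_gt(frac, 0.95)  # every co-placed cluster should hit its cell
  expect_lt(abs(sum(onCell) / nrow(cells) - 0.3), 3 * se)
})

test_that("composition percentages report both directions with audit counts", {
  # constructed truth: 40 tagged reporter cells, 10 of them FISH-positive,
  # 200 FISH cells in total
  tab <- data.frame(id = 1:40, row_px = 0, col_px = 0,
                    x_um = seq(0, 3900, 100), y_um = 0, area_um2 = 100,
                    eq_diameter_um = 11, zone = NA_character_,
                    marker_positive = NA)
  det <- new("CellDetections", table = tab,
             pixels = replicate(40, integer(0), simplify = FALSE),
             dim = c(10L, 4000L), pixelSize = 1, noSignal = FALSE)
  cells <- data.frame(id = 1:200, n_dots = 3,
                      x_um = c(seq(0, 900, 100), seq(5000, 5000 + 189 * 7, 7)),
                      y_um = 0, tagged = NA, detection_id = NA_integer_)
  fc <- new("FishCellSet", cells = cells,
            dots = data.frame(x_um = numeric(0), y_um = numeric(0)),
            membership = integer(0), clusterRadius = 5)
  fc <- tagFishCells(fc, det)
  cs <- compositionStats(fc, det)
  expect_equal(cs$pct_tagged_fish_positive, 25)
  expect_equal(cs$pct_fish_tagged, 5)
  expect_equal(cs$n_fish_positive_tagged, 10L)
  # degenerate directions: disjoint sets and zero denominators
  fcNone <- fc; fcNone@cells$tagged <- FALSE
  fcNone@cells$detection_id <- NA_integer_
  csNone <- compositionStats(fcNone, det)
  expect_equal(csNone$pct_tagged_fish_positive, 0)
  expect_equal(csNone$pct_fish_tagged, 0)
  emptyDet <- new("CellDetections", table = repquant:::emptyDetectionTable(),
                  pixels = list(), dim = c(10L, 10L), pixelSize = 1,
                  noSignal = FALSE)
  csU <- compositionStats(fcNone, emptyDet)
  expect_true(is.na(csU$pct_tagged_fish_positive))
  expect_false(csU$tagged_fish_positive_defined)
})

test_that("contribution curve matches hand computation and its invariants", {
  cc <- contributionCurve(c(10, 1, 1, 1, 1))
  expect_equal(contributorSlices(cc, 0.2), 10 / 14)
  expect_equal(cc@transcriptFraction[5], 1)
  uni <- contributionCurve(rep(4, 10))
  expect_equal(uni@transcriptFraction, uni@cellFraction)
  expect_equal(contributorSlices(uni, 0.5), 0.5)
  one <- contributionCurve(7)
  expect_equal(one@cellFraction, 1)
  expect_equal(one@transcriptFraction, 1)
  expect_error(contributionCurve(c(0, 0)), "all counts are zero")
  expect_error(contributorSlices(cc, c(0.5, 1.2)), "cutoffs")
})

test_that("descending-sort dominance holds on random count vectors", {
  withr::with_seed(211, {
    for (i in 1:100) {
      n <- sample(2:200, 1)
      counts <- rnbinom(n, mu = 5, size = runif(1, 0.2, 5))
      if (all(counts == 0)) counts[1] <- 1
      cc <- contributionCurve(counts)
      expect_true(all(cc@transcriptFraction >= cc@cellFraction - 1e-12))
      allEqual <- length(unique(cc@counts)) == 1L
      expect_equal(all(abs(cc@transcriptFraction - cc@cellFraction) < 1e-12),
                   allEqual)
      # permutation invariance
      cc2 <- contributionCurve(sample(counts))
      expect_equal(cc2@transcriptFraction, cc@transcriptFraction)
    }
  })
})
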