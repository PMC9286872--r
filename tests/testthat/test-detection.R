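test_that("to8bit rescales min-max with fixed degenerate convention", {
  m <- matrix(0:255, 16, 16)
  expect_identical(to8bit(m), matrix(as.numeric(0:255), 16, 16))
  expect_identical(to8bit(matrix(7, 4, 4)), matrix(0, 4, 4))
  ramp <- matrix(seq(0L, 65535L, length.out = 256), 16, 16)
  r8 <- to8bit(ramp)
  expect_equal(min(r8), 0)
  expect_equal(max(r8), 255)
  expect_true(all(r8 == floor(ramp / 65535 * 255 + 0.5)))
})

test_that("Otsu threshold maximizes between-class variance (oracle check)", {
  h <- numeric(256); h[c(11, 201)] <- 100   # spikes at levels 10 and 200
  expect_identical(otsuThreshold(h), bruteOtsu(h))
  # all mass at the extremes: every separating split ties; smallest wins
  h2 <- numeric(256); h2[c(1, 256)] <- 50
  expect_identical(otsuThreshold(h2), bruteOtsu(h2))
  expect_identical(otsuThreshold(h2), 0L)
  withr::with_seed(42, {
    for (i in 1:50) {
      h <- randomHistogram()
      expect_identical(otsuThreshold(h), bruteOtsu(h))
    }
  })
})

test_that("degenerate single-bin histogram is rejected", {
  h <- numeric(256); h[43] <- 10           # all mass in level 42
  expect_error(otsuThreshold(h), class = "repquant_no_separable_classes")
})

test_that("background subtraction removes offsets and keeps cell-scale disks", {
  expect_true(all(subtractBackground(matrix(50, 64, 64), 50, 2) == 0))
  img <- diskImage(100, 100, 50, 50, diamPx = 6, intensity = 150) + 50
  out <- subtractBackground(img, backgroundRadius = 50, pixelSize = 2)
  disk <- img > 50
  expect_true(all(out[disk] > 0))
  expect_true(all(out[!disk] == 0))
  withr::with_seed(1, noisy <- matrix(pmax(rnorm(64^2, 20, 10), 0), 64, 64))
  expect_lte(mean(subtractBackground(noisy, 50, 2)), mean(noisy))
  expect_error(subtractBackground(matrix(0, 10, 10), backgroundRadius = 4,
                                  pixelSize = 2), "3 pixels")
})

test_that("detectCells finds separated disks at sub-pixel accuracy", {
  rows <- c(50, 50, 150); cols <- c(50, 160, 100)
  img <- diskImage(200, 220, rows, cols, diamPx = rep(12, 3))  # 12 um at 1 um/px
  det <- detectCells(img, pixelSize = 1)
  expect_equal(nCells(det), 3L)
  tab <- cellTable(det)
  ord <- order(tab$row_px)
  expect_true(all(abs(tab$row_px[ord] - sort(rows) + 1) <= 1))
  expect_true(all(abs(tab$eq_diameter_um - 12) < 2))
})

test_that("the 10 um minimum diameter excludes small components", {
  img <- diskImage(100, 100, 50, 50, diamPx = 8)   # 8 um disk at 1 um/px
  det <- detectCells(img, pixelSize = 1)
  expect_equal(nCells(det), 0L)
  # same disk passes when the cutoff drops below its diameter
  det2 <- detectCells(img, pixelSize = 1, detectionParams(minDiameter = 7))
  expect_equal(nCells(det2), 1L)
})

test_that("a blank frame yields zero detections with the warning flag", {
  expect_warning(det <- detectCells(matrix(0, 64, 64), pixelSize = 2),
                 "no detectable signal")
  expect_equal(nCells(det), 0L)
  expect_true(det@noSignal)
})

test_that("raising minDiameter never increases the detection count", {
  sim <- generateSection(syntheticSpec(imageShape = c(512L, 512L),
                                       nCellsPerZone = c(15L, 40L, 25L, 10L, 5L),
                                       seed = 21L))
  counts <- vapply(c(6, 10, 14, 18, 22), function(md)
    nCells(detectCells(sim$image, params = detectionParams(minDiameter = md))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection count is invariant to pixel-size/resolution covariance", {
  # the same physical scene rendered at 1 um/px and at 2 um/px
  rowsUm <- c(60, 60, 180, 140); colsUm <- c(60, 170, 100, 220)
  for (ps in c(1, 2)) {
    img <- diskImage(240 / ps, 280 / ps, rowsUm / ps, colsUm / ps,
                     diamPx = rep(14 / ps, 4))
    det <- detectCells(img, pixelSize = ps)
    expect_equal(nCells(det), 4L)
  }
})

test_that("tissue mask recovers a planted ellipse area", {
  sim <- generateSection(syntheticSpec(seed = 31L))
  tm <- computeTissueMask(sim$image)
  planted <- sum(sim$truth@tissueMask) * (pixelSize(sim$image) / 1000)^2
  expect_lt(abs(maskArea(tm) - planted) / planted, 0.05)
})

test_that("tissue mask handles dark frames and keeps the largest blob only", {
  expect_warning(tm <- computeTissueMask(matrix(0, 64, 64), pixelSize = 2),
                 "empty tissue")
  expect_equal(maskArea(tm), 0)
  expect_true(tm@empty)
  img <- diskImage(300, 300, c(150, 40), c(150, 40), diamPx = c(180, 18),
                   intensity = 120)
  tm2 <- computeTissueMask(img, pixelSize = 2,
                           detectionParams(gaussianSigma = 4, closeRadius = 8))
  expect_false(tm2@mask[40, 40])       # small blob dropped
  expect_true(tm2@mask[150, 150])      # large blob retained
})
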