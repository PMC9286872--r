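smallSpec <- function(...) {
  args <- utils::modifyList(list(imageShape = c(384L, 384L),
                                 nCellsPerZone = c(10L, 25L, 15L, 8L, 4L)),
                            list(...))
  do.call(syntheticSpec, args)
}

test_that("the generator is bitwise deterministic per seed", {
  a <- generateSection(smallSpec(seed = 7L))
  b <- generateSection(smallSpec(seed = 7L))
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(a$truth@cells, b$truth@cells)
  c <- generateSection(smallSpec(seed = 8L))
  expect_false(identical(a$image@channels$reporter, c$image@channels$reporter))
})

test_that("zero requested cells yield an empty truth and a noise-only reporter", {
  sim <- generateSection(smallSpec(nCellsPerZone = rep(0L, 5), seed = 3L,
                                   noiseSd = 4))
  expect_equal(nrow(sim$truth@cells), 0L)
  expect_lt(max(sim$image@channels$reporter), 30)  # noise only, no 200-level cells
})

test_that("cells planted in one zone all carry that zone in truth and map", {
  sim <- generateSection(smallSpec(nCellsPerZone = c(0L, 50L, 0L, 0L, 0L),
                                   seed = 5L))
  cells <- sim$truth@cells
  expect_equal(nrow(cells), 50L)
  expect_true(all(cells$zone == "OSOM"))
  lab <- sim$truth@zoneMap@labels
  looked <- lab[cbind(cells$row_px + 1L, cells$col_px + 1L)]
  expect_true(all(zoneNames()[looked] == "OSOM"))
})

test_that("ground-truth invariants hold: interstitial centroids, per-zone counts", {
  spec <- smallSpec(seed = 9L)
  sim <- generateSection(spec)
  cells <- sim$truth@cells
  idx <- cbind(cells$row_px + 1L, cells$col_px + 1L)
  expect_true(all(sim$truth@tissueMask[idx]))
  expect_true(all(!sim$truth@tubuleMask[idx]))
  expect_equal(unname(vapply(zoneNames(), function(z) sum(cells$zone == z),
                             integer(1))),
               as.integer(spec@nCellsPerZone))
})

test_that("unplaceable cell requests fail with an explicit shortfall", {
  expect_error(
    generateSection(syntheticSpec(imageShape = c(64L, 64L),
                                  nCellsPerZone = c(0L, 400L, 0L, 0L, 0L),
                                  seed = 1L)),
    class = "repquant_placement_shortfall")
})

test_that("invalid zone fractions are rejected at construction", {
  expect_error(syntheticSpec(zoneBandFractions = c(0.4, 0.2, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("washout series follows the clamped line and is seed-deterministic", {
  ws <- generateWashoutSeries(54.8, 4.57, -1.0, times = c(0, 10, 20, 60, 120))
  expect_equal(ws$co_sat_pct[2], 44.8)
  expect_equal(ws$co_sat_pct[5], 4.57)          # clamped at baseline
  expect_error(generateWashoutSeries(54.8, 4.57, 0.5, times = 0:5), "negative")
  expect_error(generateWashoutSeries(3, 4.57, -1, times = 0:5), "exceed")
  a <- generateWashoutSeries(54.8, 4.57, -1, times = 0:10, noiseSd = 2, seed = 4)
  b <- generateWashoutSeries(54.8, 4.57, -1, times = 0:10, noiseSd = 2, seed = 4)
  expect_identical(a, b)
})

test_that("FISH counts approach the Poisson limit at large dispersion", {
  spec <- syntheticSpec(fishCountDispersion = 1e6, seed = 13L)
  ff <- generateFishField(spec, nCells = 1000)
  se <- sqrt(5 / 1000)   # Poisson variance = mean
  expect_lt(abs(mean(ff$cells$fish_count) - 5), 3 * se)
})

test_that("an empty FISH field has an empty dot table", {
  ff <- generateFishField(smallSpec(seed = 2L), nCells = 0)
  expect_equal(nrow(ff$dots), 0L)
  expect_equal(nrow(ff$cells), 0L)
})

test_that("separable fields cluster into exactly one cell per dot-bearing cell", {
  spec <- smallSpec(seed = 17L)
  ff <- generateFishField(spec, nCells = 150, clusterRadius = 5)
  memb <- bfsClusters(cbind(ff$dots$x_um, ff$dots$y_um), 5)
  expect_true(samePartition(memb, as.integer(factor(ff$dots$cell_id))))
  expect_equal(max(memb), length(unique(ff$dots$cell_id)))
  dotCounts <- table(ff$dots$cell_id)
  expect_equal(as.integer(dotCounts),
               ff$cells$fish_count[as.integer(names(dotCounts))])
})

test_that("impossible separable placements are flagged", {
  expect_error(
    generateFishField(syntheticSpec(imageShape = c(64L, 64L), seed = 1L),
                      nCells = 500, clusterRadius = 5),
    class = "repquant_separability_impossible")
})
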