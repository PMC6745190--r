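test_that("legends remap raw codes totally, erroring on uncovered codes", {
  # identity legend on already-classified codes is a no-op
  g <- matrix(3L, 3, 3)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_asc(mini_raster(g), tmp)
  r <- load_raster(tmp, identity_legend())
  expect_identical(r$grid, g)
  expect_equal(attr(r, "n_nodata"), 0L)

  # custom legend with nodata code, hand-counted composition
  leg <- as_legend(data.frame(raw_code = c(10, 210, 0),
                              class_name = c("cropland", "water", "nodata")))
  raw <- matrix(c(10L, 210L, 10L, 0L), 2, 2)
  cls <- remap_codes(raw, leg)
  expect_equal(sum(cls == 1L, na.rm = TRUE), 2)  # cropland
  expect_equal(sum(cls == 7L, na.rm = TRUE), 1)  # water
  expect_equal(sum(is.na(cls)), 1)

  # unmapped code is an error naming the code, never dropped
  raw[1] <- 999L
  expect_error(remap_codes(raw, leg), "999")

  # remapping an already-7-class raster with the identity legend: idempotent
  expect_identical(remap_codes(cls, identity_legend()), cls)
})

test_that("ESRI ASCII grid round-trips bitwise including nodata", {
  g <- matrix(c(1L, NA, 3L, 7L, 5L, NA), 2, 3)
  r <- lulc_raster(g, cell_area_ha = 9, xll = 10, yll = -5, cellsize = 300)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, tmp)
  back <- read_asc(tmp)
  expect_equal(back$grid, matrix(as.numeric(g), 2, 3))
  expect_equal(back$xll, 10)
  expect_equal(back$cellsize, 300)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_asc(bad), "ESRI")
})

test_that("area tabulation is count x cell-area with nodata excluded", {
  g <- matrix(2L, 10, 10)
  g[1:40] <- 1L
  a <- tabulate_areas(lulc_raster(g, cell_area_ha = 9))
  expect_equal(unname(a["cropland"]), 360)
  expect_equal(unname(a["forestland"]), 60 * 9)
  expect_equal(sum(a), 100 * 9)

  # all-nodata raster: all areas zero
  a0 <- tabulate_areas(lulc_raster(matrix(NA_integer_, 3, 3)))
  expect_true(all(a0 == 0))

  # per-cell area grid
  ca <- matrix(seq_len(4), 2, 2)
  r <- lulc_raster(matrix(c(1L, 1L, NA, 7L), 2, 2), cell_area_ha = ca)
  a2 <- tabulate_areas(r)
  expect_equal(unname(a2["cropland"]), 1 + 2)
  expect_equal(unname(a2["water"]), 4)
})

test_that("areas are conserved across epochs sharing a mask", {
  spec <- landscape_spec(rows = 40, cols = 40, patchiness = 2, seed = 3)
  r1 <- generate_initial(spec)
  r1$grid[c(5, 77, 300)] <- NA_integer_
  r2 <- evolve(r1, drift_matrix(), seed = 4)
  hz <- harmonize_masks(r1, r2)
  expect_equal(sum(tabulate_areas(hz[[1]])), sum(tabulate_areas(hz[[2]])))

  # tabulate . generate consistency: areas equal counts x cell-area exactly
  cnt <- tabulate(r1$grid[!is.na(r1$grid)], nbins = 7)
  expect_identical(as.numeric(tabulate_areas(r1)), cnt * 9)
})

test_that("area change percentages match the published change rows", {
  areas <- central_asia_areas()
  a95 <- area_row(areas, 1995, unit = "1e4_ha")
  a15 <- area_row(areas, 2015, unit = "1e4_ha")
  a35 <- area_row(areas, 2035, unit = "1e4_ha")
  expect_equal(unname(area_change_pct(a95, a95)["cropland"]), 0)
  chg <- area_change_pct(a95, a35)
  expect_equal(round(unname(chg["cropland"]), 2), 22.10)
  chg15 <- area_change_pct(a95, a15)
  expect_equal(round(unname(chg15["water"]), 2), -21.80)

  # zero baseline is flagged, not silently 0 or Inf
  z1 <- c(a95[1:6], water = 0)
  z2 <- a95
  names(z2) <- names(z1)
  flagged <- area_change_pct(z1, z2)
  expect_true(is.na(flagged["water"]))
  expect_identical(attr(flagged, "undefined"), "water")
})

test_that("mask harmonization takes the union of nodata and rejects disjoint or mismatched grids", {
  g1 <- matrix(1L, 4, 4); g1[1] <- NA
  g2 <- matrix(2L, 4, 4); g2[16] <- NA
  hz <- harmonize_masks(lulc_raster(g1), lulc_raster(g2))
  expect_true(is.na(hz[[1]]$grid[16]) && is.na(hz[[2]]$grid[1]))
  expect_equal(sum(!is.na(hz[[1]]$grid)), 14)
  expect_error(harmonize_masks(lulc_raster(g1), lulc_raster(matrix(1L, 3, 3))),
               "shape")
  gA <- matrix(NA_integer_, 2, 2); gA[1] <- 1L
  gB <- matrix(NA_integer_, 2, 2); gB[4] <- 1L
  expect_error(harmonize_masks(lulc_raster(gA), lulc_raster(gB)),
               "no common cells")
})
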