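test_that("ASCII grid round-trip preserves values, shape, cell size and nodata", {
  m <- matrix(c(1.25, NA, -3.5, 4e6, 0, 7.125, 0.1, 2, 3), 3, 3)
  g <- grid_raster(m, cell_size_m = 50, origin = c(1000, 2000))
  f <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f)
  g2 <- read_grid(f)
  expect_identical(g2$values, m)
  expect_equal(g2$cell_size_m, 50)
  expect_equal(g2$origin, c(1000, 2000))
})

test_that("ASCII grid honors a NODATA_value header on read", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 100", "NODATA_value -9999",
               "1 -9999 3", "4 5 -9999"), f)
  g <- read_grid(f)
  expect_equal(which(is.na(g$values)), which(matrix(c(1, -9999, 3, 4, 5, -9999),
                                                    2, 3, byrow = TRUE) == -9999))
  expect_equal(g$values[1, 1], 1)
  expect_equal(g$values[2, 2], 5)
})

test_that("GeoTIFF round-trip is exact for float32 data and NaN nodata", {
  set.seed(11)
  # quarter-steps are exactly representable in float32
  m <- matrix(sample(c(sample(seq(-50, 50, by = 0.25), 23), NA)), 4, 6)
  g <- grid_raster(m, cell_size_m = 100, origin = c(500000, 8600000))
  f <- withr::local_tempfile(fileext = ".tif")
  write_grid(g, f)
  g2 <- read_grid(f)
  expect_identical(is.na(g2$values), is.na(m))
  expect_identical(g2$values, m)
  expect_equal(g2$cell_size_m, 100)
  expect_equal(g2$origin, c(500000, 8600000))
})

test_that("GeoTIFF written here is read identically by an independent reader", {
  m <- matrix(as.numeric(1:12) + 0.5, 3, 4)
  m[2, 2] <- NA
  g <- grid_raster(m, cell_size_m = 100)
  f <- withr::local_tempfile(fileext = ".tif")
  write_grid(g, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", f, "');",
    "print(a.shape[0], a.shape[1]);",
    "print(' '.join(str(x) for x in np.ravel(a)))"))),
    stdout = TRUE, stderr = FALSE)
  expect_equal(out[1], "3 4")
  vals <- as.numeric(strsplit(out[2], " ")[[1]])
  expected <- as.vector(t(m))
  expect_equal(vals[!is.na(expected)], expected[!is.na(expected)])
  expect_true(all(is.nan(vals[is.na(expected)])))
})

test_that("misaligned grids are rejected with both names in the message", {
  a <- grid_raster(matrix(0, 3, 3))
  b <- grid_raster(matrix(0, 4, 3))
  expect_error(landscape_stack(alpha = a, beta = b), "alpha.*beta|beta.*alpha")
  expect_error(check_aligned(a, b, "left", "right"), "left.*right")
  expect_silent(check_aligned(a, grid_raster(matrix(1, 3, 3))))
})

test_that("distance transform matches definition on simple geometries", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  d <- distance_transform(grid_raster(m))
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[2, 3], 100)   # 4-neighbor
  expect_equal(d$values[3, 4], 100)
  expect_equal(d$values[2, 2], 100 * sqrt(2))   # diagonal
  expect_error(distance_transform(grid_raster(matrix(FALSE, 3, 3))),
               "no TRUE cells")
})

test_that("distance transform equals the brute-force oracle on random masks", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(400) < 0.08, 20, 20)
    if (!any(m)) m[7, 13] <- TRUE
    d <- distance_transform(grid_raster(m, cell_size_m = 100))
    expect_equal(d$values, bf_distance(m, 100), tolerance = 1e-12)
  }
})

test_that("distance transform ignores nodata cells entirely", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[4, 4] <- NA
  d <- distance_transform(grid_raster(m))
  expect_true(is.na(d$values[4, 4]))
  expect_equal(d$values[1, 2], 100)
})

test_that("connected patches: block, diagonal join, area and centroid accounting", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  cp <- connected_patches(grid_raster(m))
  expect_equal(nrow(cp$patches), 1)
  expect_equal(cp$patches$area_ha, 4)
  expect_equal(cp$patches$centroid_row, 2.5)
  expect_equal(cp$patches$centroid_col, 2.5)

  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(nrow(connected_patches(grid_raster(d))$patches), 1)  # 8-connectivity

  expect_equal(nrow(connected_patches(grid_raster(matrix(FALSE, 3, 3)))$patches), 0)
})

test_that("connected patches partition matches the BFS oracle on random masks", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(625) < 0.35, 25, 25)
    cp <- connected_patches(grid_raster(m))
    expect_identical(bf_partition_signature(cp$labels),
                     bf_partition_signature(bf_label(m)))
    expect_equal(sum(cp$patches$area_ha), area_ha(grid_raster(m)))
  }
})

test_that("area accounting counts only TRUE non-nodata cells", {
  expect_equal(area_ha(grid_raster(matrix(FALSE, 5, 5))), 0)
  m <- matrix(0, 5, 5); m[1:10] <- 1
  expect_equal(area_ha(grid_raster(m)), 10)
  m[3] <- NA
  expect_equal(area_ha(grid_raster(m)), 9)
  expect_equal(area_ha(grid_raster(matrix(1, 2, 2), cell_size_m = 50)), 1)
})

test_that("categorical grids round-trip with their category sidecar", {
  g <- grid_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2),
                   categories = c("forest", "cleared"))
  f <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f)
  g2 <- read_grid(f)
  expect_equal(g2$categories, c("forest", "cleared"))
})
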