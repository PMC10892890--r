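make_raster <- function(nr = 41, nc = 41, land = NULL, focal = NULL,
                        cell = 10, center = NULL) {
  v <- matrix(0, nr, nc)
  if (!is.null(land)) v[land] <- 1
  fm <- matrix(FALSE, nr, nc)
  if (!is.null(focal)) { fm[focal] <- TRUE; v[focal] <- 1 }
  land_sea_raster(v, cell_size_km = cell, focal_mask = fm, center = center)
}

test_that("all-sea and all-land rasters give the extreme isolation values", {
  sea <- make_raster(31, 31)
  expect_equal(isolation_index(sea, 100)$isolation, 1.0)

  v <- matrix(1, 31, 31)
  land <- land_sea_raster(v, cell_size_km = 10)
  expect_equal(isolation_index(land, 100)$isolation, 0.0)
})

test_that("a land block inside the disc lowers isolation by its cell count", {
  r <- make_raster(101, 101, cell = 10)
  r$values[40:44, 60:64] <- 1  # 5x5 block well inside the 300 km disc
  res <- isolation_index(r, 300)
  oracle <- oracle_isolation(r, 300)
  expect_equal(oracle$n_land, 25L)
  expect_equal(res$isolation, 1 - 25 / oracle$n_disc)
  expect_equal(res$disc_area_km2, oracle$n_disc * 100)
  expect_equal(res$neighbour_land_area_km2, 2500)
})

test_that("isolation equals brute-force enumeration on random rasters", {
  set.seed(31)
  shapes <- list(c(31, 31), c(75, 61), c(201, 201))
  for (shape in shapes) {
    v <- matrix(stats::rbinom(prod(shape), 1, 0.2), shape[1], shape[2])
    fm <- matrix(FALSE, shape[1], shape[2])
    ctr <- c((shape[1] + 1) / 2, (shape[2] + 1) / 2)
    # mark a small focal patch around the centre as the island itself
    fr <- round(ctr[1]) + (-1:1); fc <- round(ctr[2]) + (-1:1)
    v[fr, fc] <- 1; fm[fr, fc] <- TRUE
    r <- land_sea_raster(v, cell_size_km = 5, focal_mask = fm)
    radius <- 5 * (min(shape) %/% 2 - 1)
    res <- isolation_index(r, radius)
    orc <- oracle_isolation(r, radius)
    expect_equal(res$isolation, orc$isolation)
    expect_identical(res$isolation,
                     1 - res$neighbour_land_area_km2 / res$disc_area_km2)
  }
})

test_that("the focal island's own cells never count as neighbouring land", {
  base <- make_raster(41, 41, focal = cbind(20:22, 20:22))
  res <- isolation_index(base, 150)
  expect_equal(res$isolation, 1.0)  # only focal land present
})

test_that("adding land outside the focal mask never increases isolation", {
  set.seed(5)
  r <- make_raster(41, 41, focal = cbind(20:21, 20:21))
  prev <- isolation_index(r, 150)$isolation
  free <- which(r$values == 0)
  for (step in 1:10) {
    r$values[sample(free, 15)] <- 1
    free <- which(r$values == 0)
    cur <- isolation_index(r, 150)$isolation
    expect_lte(cur, prev)
    expect_gte(cur, 0); expect_lte(cur, 1)
    prev <- cur
  }
})

test_that("a disc exceeding the raster extent is a coverage error, never a truncation", {
  r <- make_raster(41, 41, cell = 10)
  expect_error(isolation_index(r, 210), class = "insula_coverage_error")
  expect_silent(isolation_index(r, 200))
})

test_that("choose_radius returns the smallest increment circumscribing the sample", {
  # focal extent ~40 km from centre -> first 100 km multiple suffices
  one <- make_raster(41, 41, focal = cbind(19:23, 19:23), cell = 10)
  expect_equal(choose_radius(list(one), 100), 100)

  # extents ~40 and ~250 km: "all" rule needs 300, "any" still 100
  big <- make_raster(121, 121, cell = 10,
                     focal = cbind(c(61, 61, 36), c(61, 86, 61)),
                     center = c(61, 61))
  idx <- which(big$focal_mask, arr.ind = TRUE)
  dist_km <- max(10 * sqrt((idx[, 1] - 61)^2 + (idx[, 2] - 61)^2))
  expect_gt(dist_km, 200); expect_lte(dist_km, 300)  # sanity of construction
  expect_equal(choose_radius(list(one, big), 100), 300)
  expect_equal(choose_radius(list(one, big), 100, rule = "any"), 100)
})

test_that("choose_radius fails with a coverage error when no multiple fits", {
  # island near the raster edge: 100 km disc already leaves the raster
  r <- make_raster(15, 15, focal = cbind(7:8, 7:8), cell = 5)
  expect_error(choose_radius(list(r), 100), class = "insula_coverage_error")
})

test_that("land/sea rasters round-trip through the grid formats", {
  r <- make_raster(31, 31, focal = cbind(15:16, 15:16), cell = 10)
  r$values[5:8, 20:25] <- 1
  p <- withr::local_tempfile(fileext = ".asc")
  write_land_sea_raster(r, p)
  r2 <- read_land_sea_raster(p, cell_size_km = 10,
                             focal_mask = r$focal_mask, center = r$center)
  expect_equal(r2$values, r$values)
  expect_equal(isolation_index(r2, 140)$isolation,
               isolation_index(r, 140)$isolation)
})

test_that("invalid raster constructions are rejected", {
  expect_error(land_sea_raster(matrix(c(0, 2, 1, 0), 2, 2), 1),
               class = "insula_validation_error")
  fm <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_error(land_sea_raster(matrix(0, 2, 2), 1, focal_mask = fm),
               class = "insula_validation_error")
})
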