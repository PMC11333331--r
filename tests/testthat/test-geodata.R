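test_that("ESRI ASCII reading lays values out north-to-south", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2", "3 4"), f)
  g <- readEsriAscii(f)
  expect_equal(gridValues(g)[1, 1], 1)  # northwest cell
  expect_equal(gridValues(g)[2, 2], 4)  # southeast cell
  expect_equal(unname(gridOrigin(g)), c(0, 0))
})

test_that("center-registered dialect converts to the corner convention", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 1", "nrows 1", "XLLCENTER -0.5", "yllcenter -0.5",
               "cellsize 1", "NODATA_value -9999", "7"), f)
  g <- readEsriAscii(f)
  expect_equal(g@xll, -1.0)
  expect_equal(g@yll, -1.0)
})

test_that("malformed grids are rejected with the offending location", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner zero", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3 4"), f)
  expect_error(readEsriAscii(f), "header line 3")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3"), f)
  expect_error(readEsriAscii(f), "row 2")
})

test_that("write/read round-trip is value-exact including nodata placement", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(round(rnorm(30), 6), 5, 6)
    v[sample(30, 5)] <- NA
    g <- rasterGrid(v, name = "rt", xll = round(runif(1, -10, 10), 2),
                    yll = round(runif(1, -10, 10), 2), cellsize = 0.25)
    f <- withr::local_tempfile(fileext = ".asc")
    writeEsriAscii(g, f)
    g2 <- readEsriAscii(f)
    expect_equal(gridValues(g2), gridValues(g))
    expect_equal(g2@xll, g@xll)
    expect_equal(g2@yll, g@yll)
    expect_equal(g2@cellsize, g@cellsize)
    expect_equal(g2@nodata, g@nodata)
  }
})

test_that("a nodata-only grid writes a data block of sentinels", {
  g <- rasterGrid(matrix(NA_real_, 2, 2))
  f <- withr::local_tempfile(fileext = ".asc")
  writeEsriAscii(g, f)
  body <- readLines(f)[7:8]
  expect_equal(body, rep("-9999 -9999", 2))
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeEsriAscii(rasterGrid(matrix(0.04, 1, 1)), f2)
  expect_equal(readLines(f2)[7], "0.04")
})

test_that("nearest extraction at cell centers equals direct indexing", {
  st <- tinyStack()
  g <- st@layers[[1]]
  d <- gridDim(g)
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    lon <- g@xll + (cc - 0.5) * g@cellsize
    lat <- g@yll + (d[1] - r + 0.5) * g@cellsize
    ev <- extractValues(st, cbind(lon, lat), method = "nearest")
    expect_equal(ev$a, gridValues(g)[r, cc])
  }
})

test_that("bilinear interpolation at the midpoint of four cells averages them", {
  v <- matrix(c(0, 10, 0, 10), 2, 2)  # north row 0,0; south row 10,10
  st <- envStack(list(rasterGrid(v, name = "z", cellsize = 1)))
  ev <- extractValues(st, cbind(1, 1), method = "bilinear")
  expect_equal(ev$z, 5.0)
})

test_that("points outside the extent and nodata hits are handled explicitly", {
  st <- tinyStack()
  expect_error(extractValues(st, cbind(-1, 0.5)), "outside")
  st2 <- envStack(list(rasterGrid(matrix(c(NA, 1, 1, 1), 2, 2),
                                  name = "a", cellsize = 1)))
  ev <- extractValues(st2, cbind(0.5, 1.5))  # NW cell is nodata
  expect_true(ev$incomplete[1])
  expect_equal(nrow(ev), 1L)  # flagged, not dropped
})

test_that("cell areas follow the cosine-latitude law", {
  g <- rasterGrid(matrix(0, 1, 1), yll = -0.5)  # centered on the equator
  expect_equal(cellAreaKm2(g, 1), (pi * 6371 / 180)^2, tolerance = 1e-12)
  expect_equal(cellAreaKm2(g, 1), 12364.3, tolerance = 1e-4)
  g60 <- rasterGrid(matrix(0, 1, 1), yll = 59.5)  # centered at 60 N
  expect_equal(cellAreaKm2(g60, 1), cellAreaKm2(g, 1) / 2)
  expect_error(cellAreaKm2(g, 2), "out of range")
})

test_that("summed cell areas over a hemisphere approach 2*pi*R^2", {
  g <- rasterGrid(matrix(0, 90, 360), xll = -180, yll = 0, cellsize = 1)
  total <- sum(cellAreaKm2(g, 1:90)) * 360
  expect_equal(total, 2 * pi * 6371^2, tolerance = 0.005)
})

test_that("occurrence CSV round-trips through the samples dialect", {
  occ <- new("OccurrenceSet", species = "Lonicera japonica",
             points = cbind(lon = c(111.9, 114.6), lat = c(32.1, 32.4)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeOccurrences(occ, f)
  expect_equal(readLines(f)[1], "species,longitude,latitude")
  occ2 <- readOccurrences(f)
  expect_equal(occPoints(occ2), occPoints(occ))
  expect_equal(occSpecies(occ2), "Lonicera japonica")
})
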