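test_that("grid_spec validates geometry and alignment is exact", {
  s <- make_spec(3, 4, 10, 20, 2.5)
  expect_equal(unname(spec_extent(s)), c(10, 20, 20, 27.5))
  expect_true(specs_aligned(s, make_spec(3, 4, 10, 20, 2.5)))
  expect_false(specs_aligned(s, make_spec(3, 4, 10, 20, 2.5, crs = "other")))
  expect_false(specs_aligned(s, make_spec(3, 4, 10.1, 20, 2.5)))
  expect_false(specs_aligned(s, make_spec(4, 4, 10, 20, 2.5)))
  expect_error(grid_spec(0, 3, 0, 0, 1))
  expect_error(grid_spec(3, 3, 0, 0, -1))
})

test_that("suitability grids enforce their declared scale", {
  expect_error(make_suit(matrix(c(0.5, 1.2), 1), scale = "unit"),
               "scale range")
  expect_silent(make_suit(matrix(c(5, 120), 1) / 2, scale = "percent"))
  expect_error(suitability_grid(matrix(0.5, 2, 2), make_spec(3, 3)),
               "dimensions")
})

test_that("normalize_scale divides percent values by 100 and is idempotent", {
  g <- make_suit(matrix(c(0, 37, 100, NA), 2), scale = "percent")
  n1 <- normalize_scale(g)
  expect_equal(n1$scale, "unit")
  expect_equal(sort(as.vector(n1$values)), c(0, 0.37, 1))
  expect_true(is.na(n1$values[2, 2]))
  # idempotence and identity on unit-scale input
  expect_identical(normalize_scale(n1), n1)
  u <- make_suit(matrix(0.37, 1, 1))
  expect_equal(normalize_scale(u)$values, u$values)
})

test_that("ASCII raster round-trip preserves spec, values and nodata", {
  set.seed(1)
  vals <- matrix(runif(12), 3, 4)
  vals[2, 3] <- NA
  g <- suitability_grid(vals, make_spec(3, 4, -10, 5, 2.5))
  path <- withr::local_tempfile(fileext = ".asc")
  write_suitability_asc(g, path)
  g2 <- read_suitability_asc(path)
  expect_true(specs_aligned(g$spec, g2$spec))
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_true(is.na(g2$values[2, 3]))
})

test_that("value scale is auto-detected from the data range", {
  unit <- make_suit(matrix(c(0.1, 0.9, 1.2, 0.3), 2) / 1.2)
  pth <- withr::local_tempfile(fileext = ".asc")
  write_suitability_asc(unit, pth)
  expect_equal(read_suitability_asc(pth)$scale, "unit")
  pct <- make_suit(matrix(c(10, 90, 55, 3), 2), scale = "percent")
  write_suitability_asc(pct, pth)
  expect_equal(read_suitability_asc(pth)$scale, "percent")
  # explicit override wins
  expect_equal(read_suitability_asc(pth, scale = "percent")$scale, "percent")
})

test_that("category rasters round-trip losslessly with a palette sidecar", {
  g <- make_category(matrix(c(1, 2, 3, NA, 2, 1), 2))
  path <- withr::local_tempfile(fileext = ".asc")
  write_category_asc(g, path)
  g2 <- read_category_asc(path)
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_equal(g2$values, g$values)
  pal <- jsonlite::read_json(paste0(path, ".palette.json"),
                             simplifyVector = TRUE)
  expect_true(all(c("1", "2", "3") %in% names(pal)))

  # trajectory raster: nine codes, nine palette entries
  codes <- matrix(trajectory_codes(), 3, 3)
  t <- trajectory_grid(codes, make_spec(3, 3))
  write_category_asc(t, path)
  t2 <- read_category_asc(path, kind = "trajectory")
  expect_equal(sort(unique(as.vector(t2$values))), sort(trajectory_codes()))
  pal9 <- jsonlite::read_json(paste0(path, ".palette.json"),
                              simplifyVector = TRUE)
  expect_length(pal9, 9)

  # a code with no palette entry is an error
  expect_error(write_category_asc(g, path, palette = c("1" = "#fff")),
               "no colour")
})

test_that("malformed rasters are rejected with explicit messages", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "0 1", "1 0"), p)
  expect_error(read_suitability_asc(p), "xllcorner")
  writeLines(c("not a raster at all"), p)
  expect_error(read_suitability_asc(p), "ASCII grid")
  expect_error(read_suitability_asc(file.path(tempdir(), "absent.asc")),
               "cannot read")
})

test_that("occurrence CSV reading drops and counts bad rows, keeps duplicates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lon,lat", "1,2", "3,4", ",5", "3,4", "6,7"), p)
  expect_message(occ <- read_occurrences_csv(p), "dropped 1")
  expect_equal(nrow(occ), 4)
  expect_equal(attr(occ, "n_dropped"), 1)
  expect_equal(sum(occ$x == 3 & occ$y == 4), 2) # duplicate retained
  expect_error(read_occurrences_csv(p, lon_col = "longitude"),
               "missing column")
  # round trip
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_occurrences_csv(occ, p2)
  occ2 <- read_occurrences_csv(p2)
  expect_equal(occ2$x, occ$x)
  expect_equal(occ2$y, occ$y)
})

test_that("zone GeoJSON round-trips ids, names and vertices", {
  z <- zone_set(
    c("a", "b"),
    list(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)),
         rbind(c(10, 10), c(12, 10), c(11, 13))),
    names = c("Zone A", "Zone B")
  )
  p <- withr::local_tempfile(fileext = ".geojson")
  write_zones_geojson(z, p)
  z2 <- read_zones_geojson(p)
  expect_equal(z2$id, z$id)
  expect_equal(z2$name, z$name)
  expect_equal(z2$polygon[[1]], z$polygon[[1]], ignore_attr = TRUE)
  expect_equal(z2$polygon[[2]], z$polygon[[2]], ignore_attr = TRUE)
  expect_error(zone_set(c("a", "a"), z$polygon[1:2]), "unique")
})

test_that("common-grid definitions persist as JSON", {
  s <- make_spec(7, 9, 100, 200, 25)
  p <- withr::local_tempfile(fileext = ".json")
  write_grid_spec_json(s, p)
  expect_true(specs_aligned(read_grid_spec_json(p), s))
})
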