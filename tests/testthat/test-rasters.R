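test_that("grid_field validates shape, mask and transform", {
  v <- matrix(1:6, 2, 3)
  f <- make_field(v * 1.0)
  expect_s3_class(f, "grid_field")
  expect_true(all(f$mask))
  expect_error(grid_field(1:5), "matrix")
  expect_error(grid_field(v * 1.0, mask = matrix(TRUE, 3, 2)), "shape")
  expect_error(grid_transform(0, 10, dx = -1), "positive")
  expect_error(grid_transform(0, 10, dx = 1, dy = 1), "negative")
  # non-finite values are masked automatically
  v2 <- v * 1.0; v2[1, 1] <- NA
  expect_equal(sum(!make_field(v2)$mask), 1)
})

test_that("masked cells are excluded from grid_values and tibble view", {
  v <- matrix(as.numeric(1:9), 3, 3)
  m <- matrix(TRUE, 3, 3); m[2, 2] <- FALSE
  f <- make_field(v, mask = m)
  expect_true(is.na(grid_values(f)[2, 2]))
  tb <- grid_to_tibble(f)
  expect_equal(nrow(tb), 9)
  expect_equal(sum(!tb$valid), 1)
  expect_equal(sum(is.na(tb$value)), 1)
})

test_that("ASCII grid round-trip preserves values, mask and transform", {
  withr::with_seed(3, {
    v <- matrix(rnorm(20), 4, 5)
  })
  m <- matrix(TRUE, 4, 5); m[c(2, 9, 17)] <- FALSE
  f <- grid_field(v, mask = m, transform = grid_transform(100, 40, 0.1),
                  variable = "AOT")
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid(f, path)
  g <- read_grid(path, variable = "AOT")
  expect_identical(g$values[g$mask], f$values[f$mask])
  expect_identical(g$mask, f$mask)
  expect_equal(g$transform$xmin, f$transform$xmin)
  expect_equal(g$transform$ymax, f$transform$ymax)
  expect_equal(g$transform$dx, f$transform$dx)
  expect_equal(g$transform$dy, f$transform$dy)
})

test_that("no-data cells in a hand-written grid file are masked", {
  lines <- c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
             "cellsize 1", "NODATA_value -9999",
             "1 2 -9999", "4 -9999 6", "-9999 8 9")
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(lines, path)
  f <- read_grid(path)
  expect_equal(sum(!f$mask), 3)
  expect_equal(f$values[1, 1], 1)
  expect_equal(f$values[3, 2], 8) # row 1 is the northernmost row
})

test_that("unreadable inputs raise distinct, named errors", {
  expect_error(read_grid("no/such/file.asc"), "does not exist")
  txt <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("this is", "just some text", "a", "b", "c", "d", "e"), txt)
  expect_error(read_grid(txt), "not an ASCII grid")
  f <- make_field(matrix(1.0, 2, 2))
  expect_error(write_grid(f, "no/such/dir/out.asc"), "parent directory")
})

test_that("write_grid avoids no-data collisions with valid values", {
  v <- matrix(c(-9999, 1, 2, 3), 2, 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid(make_field(v), path)
  g <- read_grid(path)
  expect_true(all(g$mask))
  expect_identical(sort(as.vector(g$values)), sort(as.vector(v)))
})

test_that("align_check passes on co-registered stacks and is symmetric", {
  a <- make_field(matrix(0, 10, 10))
  b <- make_field(matrix(1, 10, 10))
  expect_true(align_check(list(a, b)))
  expect_true(align_check(list(b, a)))
  expect_true(align_check(list(a, a))) # reflexive
  c_wrong <- make_field(matrix(0, 10, 11))
  expect_error(align_check(list(a, c_wrong)), "alignment error.*10x10",
               ignore.case = TRUE)
  expect_error(align_check(list(c_wrong, a)), "alignment error")
  shifted <- grid_field(matrix(0, 10, 10),
                        transform = grid_transform(0.5, 10, 1))
  expect_error(align_check(list(a, shifted)), "transform")
  zones_bad <- zone_mask(matrix(1L, 9, 10), transform = unit_transform(9))
  expect_error(align_check(list(a), zones = zones_bad), "zone mask")
})

test_that("zone masks validate labels and round-trip through files", {
  labels <- matrix(c(1L, 1L, 2L, 0L), 2, 2)
  z <- zone_mask(labels, zone_names = c("1" = "north", "2" = "south"),
                 transform = unit_transform(2))
  expect_error(zone_mask(matrix(-1L, 2, 2)), "non-negative")
  expect_error(zone_mask(labels, zone_names = c("1" = "north")),
               "absent from zone_names")
  path <- withr::local_tempfile(fileext = ".asc")
  write_zones(z, path)
  z2 <- read_zones(path)
  expect_identical(z2$labels, z$labels)
  expect_identical(z2$zone_names, z$zone_names)
})

test_that("station CSVs are validated and dirty rows handled by policy", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,lat,lon,pollutant,observed_pm,AOT,RH",
    "a,30,110,PM2.5,55,0.4,60",
    "b,31,111,PM2.5,not_a_number,0.5,61",
    "c,32,112,PM2.5,60,,62",
    "d,33,113,PM2.5,70,0.6,63"
  ), path)
  expect_warning(
    expect_message(tab <- read_stations(path), "dropped 1"),
    "non-numeric observed_pm.*rows 2")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "predictors"), c("AOT", "RH"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lat,lon,pollutant,AOT", "a,30,110,PM2.5,0.4"), bad)
  expect_error(read_stations(bad), "observed_pm")
  expect_error(as_station_table(tibble::tibble(id = "a")), "mandatory")
})
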