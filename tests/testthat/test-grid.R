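test_that("cell areas follow the spherical closed form and sum to the sphere", {
  sp <- grid_spec()
  # equator-adjacent 0.5 deg band, evaluated from the closed form by hand
  expected <- 6371^2 * (0.5 * pi / 180) * (sin(0.5 * pi / 180) - sin(0))
  expect_equal(cell_area(181, sp), expected, tolerance = 1e-12)
  expect_equal(round(cell_area(181, sp)), 3091)

  # polemost band: smallest but strictly positive
  areas <- cell_area(seq_len(sp$n_lat), sp)
  expect_gt(min(areas), 0)
  expect_equal(min(areas), areas[1])        # polemost bands are the smallest
  expect_equal(areas[sp$n_lat], areas[1], tolerance = 1e-12)

  # symmetry about the equator
  expect_equal(areas, rev(areas), tolerance = 1e-12)

  # sum over all cells = 4 pi R^2 within 1e-6 relative
  for (spec in list(sp, coarse_spec())) {
    total <- sum(cell_area_field(spec))
    expect_lt(abs(total / (4 * pi * 6371^2) - 1), 1e-6)
  }

  expect_error(cell_area(0, sp), "out of range")
  expect_error(cell_area(361, sp), "out of range")
})

test_that("grid_spec validates its geometry", {
  expect_error(grid_spec(36, 72, 0.5), "n_lat")
  expect_error(grid_spec(360, 100, 0.5), "n_lon")
  sp <- grid_spec(36, 72, 5)
  expect_equal(sp$lat[1], -87.5)
  expect_equal(range(grid_spec()$lat), c(-89.75, 89.75))
  expect_equal(grid_spec()$lon[1], -179.75)
})

test_that("area-weighted totals convert per-m2 rates to Tg", {
  sp <- coarse_spec()
  f1 <- grid_field(1, sp, "g m-2 yr-1")
  expect_equal(area_weighted_total(f1), 4 * pi * 6371^2 * 1e6 * 1e-12,
               tolerance = 1e-12)
  expect_equal(round(area_weighted_total(f1), 2), 510.06)

  expect_equal(area_weighted_total(grid_field(0, sp, "g m-2 yr-1")), 0)

  # single non-missing equator-adjacent cell of 1 g m-2 yr-1
  v <- matrix(NA_real_, sp$n_lat, sp$n_lon)
  v[19, 1] <- 1  # 0..5N band on the coarse grid
  single <- area_weighted_total(grid_field(v, sp, "g m-2 yr-1"))
  expect_equal(single, cell_area(19, sp) * 1e6 * 1e-12, tolerance = 1e-12)

  # on the 0.5 deg grid the equatorial cell gives ~3.091e-3 Tg
  sp2 <- grid_spec()
  v2 <- matrix(NA_real_, sp2$n_lat, sp2$n_lon)
  v2[181, 1] <- 1
  expect_equal(area_weighted_total(grid_field(v2, sp2, "g m-2 yr-1")),
               3.091e-3, tolerance = 1e-4)

  expect_error(area_weighted_total(grid_field(1, sp, "degC")),
               "not a per-m2 rate")
})

test_that("regional totals partition the global total", {
  sp <- coarse_spec()
  set.seed(11)
  f <- grid_field(matrix(runif(sp$n_lat * sp$n_lon), sp$n_lat), sp,
                  "g m-2 yr-1")
  regions <- synthetic_regions(sp)
  parts <- vapply(regions$levels,
                  function(lb) area_weighted_total(f, regions, lb),
                  numeric(1))
  expect_lt(abs(sum(parts) / area_weighted_total(f) - 1), 1e-9)
  expect_error(area_weighted_total(f, regions, "Atlantis"), "unknown region")
})

test_that("NetCDF and CSV field I/O round-trip bit-exactly", {
  sp <- coarse_spec()
  set.seed(3)
  v <- matrix(rnorm(sp$n_lat * sp$n_lon), sp$n_lat)
  v[1, 5] <- NA  # an ocean cell survives the round trip as missing
  f <- grid_field(v, sp, "g m-2 yr-1", name = "flux")

  for (ext in c(".nc", ".csv")) {
    path <- tempfile(fileext = ext)
    write_field(f, path)
    g <- read_field(path, sp)
    expect_identical(g$values, f$values)
    expect_identical(g$units, "g m-2 yr-1")
    expect_identical(g$name, "flux")
    unlink(path)
  }
})

test_that("field I/O rejects mismatched grids and degrades missing units", {
  f1deg <- grid_field(1, grid_spec(180, 360, 1), "g m-2 yr-1")
  path <- tempfile(fileext = ".nc")
  write_field(f1deg, path)
  expect_error(read_field(path, grid_spec()), "does not match")
  unlink(path)

  # NetCDF with no units attribute -> units "unknown" with a warning
  sp <- coarse_spec()
  path <- tempfile(fileext = ".nc")
  dl <- ncdf4::ncdim_def("lon", "degrees_east", sp$lon)
  dla <- ncdf4::ncdim_def("lat", "degrees_north", sp$lat)
  var <- ncdf4::ncvar_def("x", "", list(dl, dla), prec = "double")
  nc <- ncdf4::nc_create(path, var)
  ncdf4::ncvar_put(nc, var, t(matrix(1, sp$n_lat, sp$n_lon)))
  ncdf4::nc_close(nc)
  expect_warning(g <- read_field(path, sp), "unknown")
  expect_identical(g$units, "unknown")
  unlink(path)

  expect_error(read_field(tempfile(fileext = ".nc"), sp))
})
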