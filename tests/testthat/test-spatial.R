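# Gridded runs: NetCDF round trips, per-cell equivalence with scalar runs,
# food-response monotonicity of the suitability maps, and fill-value
# semantics.

# build a small clam forcing NetCDF: temperature + chlorophyll cycles with
# a per-cell offset so cells differ
make_clam_grid <- function(path, nlat = 2, nlon = 2, n_days = 120,
                           start = "2015-04-01", chl_scale = 1) {
  lat <- seq(44, by = 0.1, length.out = nlat)
  lon <- seq(12, by = 0.1, length.out = nlon)
  d <- 0:(n_days - 1)
  temp <- array(0, c(nlat, nlon, n_days))
  chl <- array(0, c(nlat, nlon, n_days))
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    temp[i, j, ] <- 16 + 6 * sin(2 * pi * d / 365) + 0.1 * i
    chl[i, j, ] <- chl_scale * (2 + 0.5 * j + sin(2 * pi * d / 120))
  }
  write_gridded_forcings(path, lat, lon, as.Date(start),
                         list(temperature = temp, chlorophyll = chl))
  list(lat = lat, lon = lon, temp = temp, chl = chl)
}

test_that("gridded forcings round-trip through NetCDF exactly", {
  nc <- withr::local_tempfile(fileext = ".nc")
  ref <- make_clam_grid(nc)
  g <- read_gridded_forcings(nc, "clam")
  expect_equal(g$domain$lat, ref$lat)
  expect_equal(g$domain$lon, ref$lon)
  expect_equal(g$start, as.Date("2015-04-01"))
  for (i in 1:2) for (j in 1:2) {
    b <- g$bundle_at(i, j)
    expect_equal(b$series$temperature$values, ref$temp[i, j, ])
    expect_equal(b$series$chlorophyll$values, ref$chl[i, j, ])
  }
})

test_that("a 1x1 grid reproduces the tabular forcing path", {
  nc <- withr::local_tempfile(fileext = ".nc")
  ref <- make_clam_grid(nc, nlat = 1, nlon = 1)
  g <- read_gridded_forcings(nc, "clam")
  b_grid <- g$bundle_at(1, 1)
  b_tab <- forcing_bundle("clam", list(
    temperature = forcing_series("temperature", as.Date("2015-04-01"),
                                 ref$temp[1, 1, ]),
    chlorophyll = forcing_series("chlorophyll", as.Date("2015-04-01"),
                                 ref$chl[1, 1, ])))
  expect_equal(b_grid$series$temperature$values,
               b_tab$series$temperature$values)
  hd <- g$start + g$n_days - 1
  expect_equal(
    simulate_individual("clam", bundle = b_grid, seed_day = g$start,
                        harvest_day = hd)$state,
    simulate_individual("clam", bundle = b_tab, seed_day = g$start,
                        harvest_day = hd)$state)
})

test_that("mussel grids accept imposed literature constants", {
  nc <- withr::local_tempfile(fileext = ".nc")
  lat <- c(44, 44.1); lon <- c(12, 12.1)
  nd <- 60
  temp <- array(rep(16, 2 * 2 * nd), c(2, 2, nd))
  chl <- array(rep(2, 2 * 2 * nd), c(2, 2, nd))
  write_gridded_forcings(nc, lat, lon, as.Date("2015-09-05"),
                         list(temperature = temp, chlorophyll = chl))
  g <- read_gridded_forcings(nc, "mussel",
                             constants = c(tsm = 6, pom = 1.2, poc = 0.5,
                                           poc_cp = 106, poc_np = 16))
  b <- g$bundle_at(2, 1)
  expect_s3_class(b, "forcing_bundle")
  expect_equal(b$series$poc$values, rep(0.5, nd))
  # missing variable without a constant is a schema error
  expect_error(read_gridded_forcings(nc, "mussel",
                                     constants = c(tsm = 6, pom = 1.2)),
               "schema error")
})

test_that("grid runs are identical to independent per-cell scalar runs", {
  nc <- withr::local_tempfile(fileext = ".nc")
  make_clam_grid(nc, nlat = 3, nlon = 3)
  g <- read_gridded_forcings(nc, "clam")
  out <- run_grid("clam", gridded = g, thresholds = c(10, 25))
  for (i in 1:3) for (j in 1:3) {
    tr <- simulate_individual("clam", bundle = g$bundle_at(i, j),
                              seed_day = g$start,
                              harvest_day = g$start + g$n_days - 1)
    expect_identical(out$weight[i, j, ], unname(tr$state[, "w"]))
    expect_identical(out$length[i, j, ], unname(tr$length))
    expect_identical(out$days_to_size[i, j, 1],
                     as.numeric(days_to_size(tr, 10, "length")))
  }
  expect_true(all(out$status == "ok"))
})

test_that("uniform cells give identical trajectories across the grid", {
  nc <- withr::local_tempfile(fileext = ".nc")
  lat <- c(44, 44.1); lon <- c(12, 12.1)
  nd <- 90
  temp <- array(18, c(2, 2, nd)); chl <- array(3, c(2, 2, nd))
  write_gridded_forcings(nc, lat, lon, as.Date("2015-04-01"),
                         list(temperature = temp, chlorophyll = chl))
  g <- read_gridded_forcings(nc, "clam")
  out <- run_grid("clam", gridded = g)
  for (i in 1:2) for (j in 1:2) {
    expect_identical(out$weight[i, j, ], out$weight[1, 1, ])
  }
  tr <- simulate_individual("clam", bundle = g$bundle_at(1, 1),
                            seed_day = g$start,
                            harvest_day = g$start + nd - 1)
  expect_identical(out$weight[1, 1, ], unname(tr$state[, "w"]))
})

test_that("doubling chlorophyll never slows reaching commercial size", {
  nc1 <- withr::local_tempfile(fileext = ".nc")
  nc2 <- withr::local_tempfile(fileext = ".nc")
  make_clam_grid(nc1, nlat = 3, nlon = 3, n_days = 380)
  make_clam_grid(nc2, nlat = 3, nlon = 3, n_days = 380, chl_scale = 2)
  o1 <- run_grid("clam", gridded = read_gridded_forcings(nc1, "clam"),
                 thresholds = 20)
  o2 <- run_grid("clam", gridded = read_gridded_forcings(nc2, "clam"),
                 thresholds = 20)
  d1 <- o1$days_to_size[, , 1]
  d2 <- o2$days_to_size[, , 1]
  reached <- !is.na(d1)
  expect_true(all(!is.na(d2[reached])))
  expect_true(all(d2[reached] <= d1[reached]))
})

test_that("output NetCDF carries fill values for land and not-reached", {
  nc_in <- withr::local_tempfile(fileext = ".nc")
  nc_out <- withr::local_tempfile(fileext = ".nc")
  make_clam_grid(nc_in, nlat = 2, nlon = 2, n_days = 100)
  g <- read_gridded_forcings(nc_in, "clam")
  g$domain$mask[2, 2] <- FALSE            # pretend one land cell
  out <- run_grid("clam", gridded = g, thresholds = c(8, 60))
  write_gridded_outputs(out, nc_out)

  h <- ncdf4::nc_open(nc_out)
  on.exit(ncdf4::nc_close(h))
  dts <- ncdf4::ncvar_get(h, "days_to_size", collapse_degen = FALSE)
  flag <- ncdf4::ncvar_get(h, "flag", collapse_degen = FALSE)
  w <- ncdf4::ncvar_get(h, "weight", collapse_degen = FALSE)
  # ncvar_get maps the declared fill value to NA; land cell is NA all over
  expect_true(all(is.na(w[2, 2, ])))
  expect_equal(flag[2, 2, 1], 2)
  # a 60 mm clam is unreachable in 100 days: not-reached flag everywhere
  expect_true(all(is.na(dts[, , 2])))
  expect_true(all(flag[1:2, 1, 2] == 1))
  # reached cells round-trip the in-memory map
  expect_equal(dts[1, 1, 1], out$days_to_size[1, 1, 1])
  # read-back trajectories equal in-memory values (sea cells)
  expect_equal(w[1, 1, ], out$weight[1, 1, ])
})

test_that("size maps export as long-format CSV with empty not-reached", {
  nc_in <- withr::local_tempfile(fileext = ".nc")
  make_clam_grid(nc_in, nlat = 2, nlon = 2, n_days = 100)
  out <- run_grid("clam", gridded = read_gridded_forcings(nc_in, "clam"),
                  thresholds = c(8, 60))
  f <- withr::local_tempfile(fileext = ".csv")
  write_size_maps_csv(out, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_true(all(is.na(tab$days[tab$threshold == 60])))
})
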