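# Cell-by-cell runs of the individual model over a gridded forcing domain
# and NetCDF I/O of the resulting days-to-commercial-size maps.

FILL_VALUE <- -9999

#' Define a rectangular lat/lon grid domain
#'
#' @param lat,lon Strictly monotone coordinate vectors (cell centres).
#' @param mask Logical matrix `(lat, lon)`: `TRUE` = sea (simulated),
#'   `FALSE` = land (skipped). Default: all sea.
#' @return Object of class `grid_domain`.
#' @export
grid_domain <- function(lat, lon, mask = NULL) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  mono <- function(x) length(x) == 1 || all(diff(x) > 0) || all(diff(x) < 0)
  if (!mono(lat) || !mono(lon)) {
    stop("lat and lon must be strictly monotone")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, length(lat), length(lon))
  }
  if (!is.logical(mask) || !all(dim(mask) == c(length(lat), length(lon)))) {
    stop("mask must be a logical (lat, lon) matrix")
  }
  structure(list(lat = lat, lon = lon, mask = mask), class = "grid_domain")
}

#' Write synthetic gridded forcings to a NetCDF file
#'
#' Helper for building test/demo inputs for [read_gridded_forcings()]:
#' stores per-variable arrays with dims `(lon, lat, time)` plus a CF-style
#' `time` coordinate (`days since <start>`).
#'
#' @param path Output NetCDF path.
#' @param lat,lon Coordinate vectors.
#' @param start First day (`Date`).
#' @param arrays Named list of numeric arrays `(lat, lon, time)`; names are
#'   forcing series names (e.g. `temperature`, `chlorophyll`).
#' @return `path`, invisibly.
#' @export
write_gridded_forcings <- function(path, lat, lon, start, arrays) {
  start <- as.Date(start)
  nt <- dim(arrays[[1]])[3]
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", as.double(lon))
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", as.double(lat))
  dtime <- ncdf4::ncdim_def("time",
                            paste("days since", format(start, "%Y-%m-%d")),
                            as.double(0:(nt - 1)))
  vars <- lapply(names(arrays), function(nm) {
    ncdf4::ncvar_def(nm, forcing_units[[nm]], list(dlon, dlat, dtime),
                     missval = FILL_VALUE, prec = "double")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(arrays)) {
    # (lat, lon, time) -> (lon, lat, time)
    ncdf4::ncvar_put(nc, vars[[i]], aperm(arrays[[i]], c(2, 1, 3)))
  }
  invisible(path)
}

#' Read gridded forcings from a NetCDF dataset
#'
#' Opens a `(time, lat, lon)` NetCDF dataset and returns the grid domain
#' plus a factory producing the validated per-cell [forcing_bundle()].
#' Forcing variables that are not present in the file (e.g. the literature
#' TSM/POM/POC values of the mussel model) are imposed as spatially uniform
#' constants through `constants`. Cells where any forcing variable is the
#' fill value on any day are masked out.
#'
#' @param path NetCDF file path.
#' @param species Species name.
#' @param var_map Named character vector mapping forcing series names to
#'   NetCDF variable names (default: identical names).
#' @param constants Named numeric of constant forcings broadcast over the
#'   grid.
#' @param feed_composition Finfish feed composition.
#' @return List with `domain` (a `grid_domain`), `start` (`Date`),
#'   `n_days`, and `bundle_at(i, j)` returning the `forcing_bundle` of cell
#'   `(lat_i, lon_j)`.
#' @export
read_gridded_forcings <- function(path, species, var_map = NULL,
                                  constants = NULL,
                                  feed_composition = NULL) {
  species <- match_species(species)
  req <- forcing_requirements(species)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!all(c("lat", "lon", "time") %in% names(nc$dim))) {
    stop("schema error: NetCDF dataset needs lat, lon and time dimensions")
  }
  lat <- nc$dim$lat$vals; lon <- nc$dim$lon$vals
  tunits <- nc$dim$time$units
  if (!grepl("^days since ", tunits)) {
    stop("schema error: time units must be 'days since YYYY-MM-DD'")
  }
  start <- as.Date(sub("^days since ", "", tunits)) + nc$dim$time$vals[1]
  n_days <- length(nc$dim$time$vals)

  from_file <- setdiff(req, names(constants))
  fields <- list()
  for (nm in from_file) {
    vn <- if (!is.null(var_map) && nm %in% names(var_map)) var_map[[nm]]
          else nm
    if (!vn %in% names(nc$var)) {
      stop("schema error: variable '", vn, "' (forcing '", nm,
           "') missing from ", path)
    }
    a <- ncdf4::ncvar_get(nc, vn, collapse_degen = FALSE)  # (lon, lat, time)
    a[!is.finite(a) | a == FILL_VALUE] <- NA
    fields[[nm]] <- a
  }

  valid <- matrix(TRUE, length(lat), length(lon))
  for (a in fields) {
    ok <- t(apply(!is.na(a), c(1, 2), all))   # -> (lat, lon)
    valid <- valid & ok
  }
  domain <- grid_domain(lat, lon, valid)

  bundle_at <- function(i, j) {
    series <- list()
    for (nm in req) {
      v <- if (nm %in% names(fields)) fields[[nm]][j, i, ]
           else rep(constants[[nm]], n_days)
      series[[nm]] <- forcing_series(nm, start, v)
    }
    fc <- if (is_finfish(species)) {
      if (is.null(feed_composition)) default_feed_composition()
      else feed_composition
    } else NULL
    forcing_bundle(species, series, fc)
  }

  list(domain = domain, start = start, n_days = n_days,
       bundle_at = bundle_at)
}

#' Run the individual model over every cell of a gridded domain
#'
#' Each unmasked cell is simulated independently with
#' [simulate_individual()] on its own forcing bundle; cells therefore share
#' no state and the result is invariant to the order in which they are
#' visited. Days-to-commercial-size is computed per threshold per cell; a
#' cell-level failure is recorded (fill value plus message) without
#' aborting the grid.
#'
#' @param species Species name.
#' @param params `species_params`.
#' @param gridded Result of [read_gridded_forcings()] (or an equivalent
#'   list with `domain`, `start`, `n_days`, `bundle_at`).
#' @param seed_day,harvest_day Rearing window (`Date`); defaults to the
#'   full forcing window.
#' @param initial_state Seeding state (default per species).
#' @param thresholds Commercial-size thresholds (default per species, e.g.
#'   5 and 7 cm for the mussel).
#' @return Object of class `gridded_outputs`: `domain`, `days`, `weight`
#'   and (shellfish) `length` arrays `(lat, lon, time)`, `days_to_size`
#'   array `(lat, lon, threshold)` with `NA` where the size was not
#'   reached, `status` matrix (`"ok"`, `"land"`, or an error message) and
#'   the thresholds/metric used.
#' @export
run_grid <- function(species, params = species_params(species), gridded,
                     seed_day = NULL, harvest_day = NULL,
                     initial_state = default_initial_state(species),
                     thresholds = NULL) {
  species <- match_species(species)
  domain <- gridded$domain
  if (is.null(seed_day)) seed_day <- gridded$start
  if (is.null(harvest_day)) {
    harvest_day <- gridded$start + gridded$n_days - 1
  }
  seed_day <- as.Date(seed_day); harvest_day <- as.Date(harvest_day)
  thr <- default_thresholds(species, params)
  if (!is.null(thresholds)) thr$thresholds <- thresholds

  nlat <- length(domain$lat); nlon <- length(domain$lon)
  nt <- as.integer(harvest_day - seed_day) + 1L
  weight <- array(NA_real_, c(nlat, nlon, nt))
  len <- if (!is_finfish(species)) array(NA_real_, c(nlat, nlon, nt))
  dmap <- array(NA_real_, c(nlat, nlon, length(thr$thresholds)))
  status <- matrix("land", nlat, nlon)

  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (!domain$mask[i, j]) next
      res <- tryCatch({
        traj <- simulate_individual(species, params, gridded$bundle_at(i, j),
                                    seed_day = seed_day,
                                    harvest_day = harvest_day,
                                    initial_state = initial_state)
        weight[i, j, ] <- rowSums(traj$state)
        if (!is.null(len)) len[i, j, ] <- traj$length
        dmap[i, j, ] <- vapply(thr$thresholds, function(x) {
          as.numeric(days_to_size(traj, x, thr$metric))
        }, numeric(1))
        "ok"
      }, error = function(e) conditionMessage(e))
      status[i, j] <- res
    }
  }
  structure(list(domain = domain, seed_day = seed_day,
                 harvest_day = harvest_day, days = 0:(nt - 1),
                 weight = weight, length = len, days_to_size = dmap,
                 thresholds = thr$thresholds, metric = thr$metric,
                 status = status),
            class = "gridded_outputs")
}

#' Write gridded model outputs to a NetCDF file
#'
#' CF-style output: coordinate variables with units, declared fill value
#' for both land cells and sizes not reached within the window, plus a
#' `flag` variable distinguishing them (0 = ok, 1 = not reached within the
#' simulated window, 2 = land/failed cell).
#'
#' @param out A `gridded_outputs`.
#' @param path Output NetCDF path.
#' @return `path`, invisibly.
#' @export
write_gridded_outputs <- function(out, path) {
  stopifnot(inherits(out, "gridded_outputs"))
  d <- out$domain
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", as.double(d$lon))
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", as.double(d$lat))
  dtime <- ncdf4::ncdim_def("time",
                            paste("days since",
                                  format(out$seed_day, "%Y-%m-%d")),
                            as.double(out$days))
  dthr <- ncdf4::ncdim_def("threshold", "size", as.double(out$thresholds))

  vars <- list(
    weight = ncdf4::ncvar_def("weight", "g", list(dlon, dlat, dtime),
                              missval = FILL_VALUE, prec = "double"),
    days_to_size = ncdf4::ncvar_def(
      "days_to_size", "days", list(dlon, dlat, dthr),
      missval = FILL_VALUE, prec = "double"),
    flag = ncdf4::ncvar_def("flag", "", list(dlon, dlat, dthr),
                            missval = -1, prec = "integer"))
  if (!is.null(out$length)) {
    vars$length <- ncdf4::ncvar_def("length",
                                    if (out$metric == "length") "cm" else "",
                                    list(dlon, dlat, dtime),
                                    missval = FILL_VALUE, prec = "double")
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))

  put <- function(var, a) {
    a[is.na(a)] <- FILL_VALUE
    ncdf4::ncvar_put(nc, var, aperm(a, c(2, 1, 3)))
  }
  put(vars$weight, out$weight)
  if (!is.null(out$length)) put(vars$length, out$length)
  put(vars$days_to_size, out$days_to_size)

  flag <- array(0L, dim(out$days_to_size))
  for (k in seq_along(out$thresholds)) {
    land <- out$status != "ok"
    nr <- is.na(out$days_to_size[, , k]) & !land
    flag[, , k][nr] <- 1L
    flag[, , k][land] <- 2L
  }
  ncdf4::ncvar_put(nc, vars$flag, aperm(flag, c(2, 1, 3)))
  invisible(path)
}

#' Export days-to-size maps as a long-format CSV
#'
#' @param out A `gridded_outputs`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_size_maps_csv <- function(out, path) {
  stopifnot(inherits(out, "gridded_outputs"))
  d <- out$domain
  rows <- expand.grid(lat = d$lat, lon = d$lon,
                      threshold = out$thresholds)
  rows$days <- as.vector(out$days_to_size)
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}
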