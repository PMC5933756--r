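# Forcing time series: reading, daily interpolation, validation and the
# synthetic-forcing generator used for demos and tests.

forcing_units <- c(
  temperature = "degC",
  chlorophyll = "ug/l",
  poc         = "mgC/l",
  pom         = "mg/l",
  tsm         = "mg/l",
  poc_cp      = "molC/molP",
  poc_np      = "molN/molP",
  ration      = "g/d",
  phyto_c     = "mgC/l",
  det_zoo_c   = "mgC/l"
)

# concentration-type names that must be >= 0 after preprocessing
nonneg_forcings <- c("chlorophyll", "poc", "pom", "tsm", "poc_cp", "poc_np",
                     "ration", "phyto_c", "det_zoo_c")

#' Forcing series required by each species
#'
#' Mussels need the full suite of food descriptors (temperature,
#' chlorophyll-a, TSM, POM, POC plus the POC C/P and N/P molar ratios);
#' clams need temperature and chlorophyll-a; the two finfish need
#' temperature and a feed ration series (with a constant feed composition).
#'
#' @param species Species name.
#' @return Character vector of series names.
#' @export
forcing_requirements <- function(species) {
  species <- match_species(species)
  switch(species,
    mussel = c("temperature", "chlorophyll", "tsm", "pom", "poc",
               "poc_cp", "poc_np"),
    clam = c("temperature", "chlorophyll"),
    seabass = ,
    seabream = c("temperature", "ration"))
}

#' Construct a raw (possibly unequally spaced) forcing series
#'
#' @param name Series name (one of the names in [forcing_requirements()]).
#' @param dates `Date` vector, strictly increasing.
#' @param values Numeric vector, finite, same length as `dates`.
#' @param units Units string; defaults to the canonical units for `name`.
#' @return Object of class `raw_series`.
#' @export
raw_series <- function(name, dates, values, units = NULL) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stop("dates and values must have equal length")
  }
  if (length(dates) < 2) {
    stop("insufficient data: series '", name, "' needs at least 2 records")
  }
  if (anyNA(dates)) stop("unparseable dates in series '", name, "'")
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("dates of series '", name,
         "' must be strictly increasing (no duplicates)")
  }
  if (any(!is.finite(values))) {
    stop("non-finite values in series '", name, "'")
  }
  if (is.null(units)) units <- forcing_units[[name]]
  structure(list(name = name, dates = dates, values = values, units = units),
            class = "raw_series")
}

#' Read a forcing table from a CSV file
#'
#' Expects a two-column table with header `date,value`, ISO-8601 dates,
#' dot decimal separator. Rows must be strictly increasing in date.
#'
#' @param source Path or connection to the CSV file.
#' @param name Name to give the series.
#' @param units Optional units override.
#' @param date_format Date format string (default ISO `"%Y-%m-%d"`).
#' @return A `raw_series`.
#' @export
read_forcing_table <- function(source, name, units = NULL,
                               date_format = "%Y-%m-%d") {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE,
                         strip.white = TRUE, colClasses = "character")
  if (!all(c("date", "value") %in% names(tab))) {
    stop("forcing table for '", name, "' must have columns date,value")
  }
  if (nrow(tab) < 2) {
    stop("insufficient data: forcing table for '", name,
         "' has fewer than 2 rows")
  }
  dates <- as.Date(tab$date, format = date_format)
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop("unparseable date '", tab$date[bad], "' at row ", bad,
         " of series '", name, "'")
  }
  values <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1]
    stop("unparseable value '", tab$value[bad], "' at row ", bad,
         " of series '", name, "'")
  }
  raw_series(name, dates, values, units = units)
}

#' Write a raw forcing series as a CSV table
#'
#' Inverse of [read_forcing_table()]; round-trips values exactly (full
#' double precision).
#'
#' @param raw A `raw_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcing_table <- function(raw, path) {
  stopifnot(inherits(raw, "raw_series"))
  tab <- data.frame(date = format(raw$dates, "%Y-%m-%d"),
                    value = format(raw$values, digits = 17, trim = TRUE,
                                   scientific = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a raw series onto a daily grid
#'
#' Piecewise-linear interpolation onto one value per calendar day over
#' `[start, end]`. Values at original record dates are preserved exactly;
#' no extrapolation is performed — the raw series must cover the window.
#'
#' @param raw A `raw_series`.
#' @param start,end First and last day of the simulation window (`Date`).
#' @return Object of class `forcing_series`: list with `name`, `start`
#'   (Date), `values` (one per day, `end - start + 1` entries) and `units`.
#' @export
interpolate_daily <- function(raw, start, end) {
  stopifnot(inherits(raw, "raw_series"))
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date precedes start date")
  if (raw$dates[1] > start || raw$dates[length(raw$dates)] < end) {
    stop("coverage error: series '", raw$name, "' covers [",
         raw$dates[1], ", ", raw$dates[length(raw$dates)],
         "] but [", start, ", ", end, "] was requested (no extrapolation)")
  }
  grid <- seq(start, end, by = "day")
  vals <- stats::approx(x = as.numeric(raw$dates), y = raw$values,
                        xout = as.numeric(grid), method = "linear",
                        ties = "ordered")$y
  forcing_series(raw$name, start, vals, raw$units)
}

#' Construct a daily forcing series
#'
#' @param name Series name.
#' @param start First day (`Date`).
#' @param values Numeric vector, one value per day, all finite.
#' @param units Units string; defaults to the canonical units for `name`.
#' @return Object of class `forcing_series`.
#' @export
forcing_series <- function(name, start, values, units = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1 || any(!is.finite(values))) {
    stop("forcing series '", name, "' must have >= 1 finite values")
  }
  if (is.null(units)) units <- forcing_units[[name]]
  structure(list(name = name, start = as.Date(start), values = values,
                 units = units),
            class = "forcing_series")
}

#' Derive mussel food fractions from chlorophyll-a and POC
#'
#' Phytoplankton carbon is chlorophyll-a times a fixed carbon-to-chlorophyll
#' ratio (with the ug/l to mgC/l unit conversion applied); the
#' detritus + zooplankton carbon pool is the remainder of the POC after
#' subtracting phytoplankton carbon, clipped at zero.
#'
#' @param chl Daily chlorophyll-a series (ug/l).
#' @param poc Daily particulate organic carbon series (mgC/l).
#' @param c_to_chl Carbon-to-chlorophyll mass ratio (g C per g chl),
#'   default 50.
#' @return List with `phyto_c` and `det_zoo_c` daily series (mgC/l) on the
#'   same grid as the inputs.
#' @export
derive_mussel_food <- function(chl, poc, c_to_chl = 50) {
  stopifnot(inherits(chl, "forcing_series"), inherits(poc, "forcing_series"))
  if (c_to_chl <= 0) stop("c_to_chl must be > 0")
  if (chl$start != poc$start || length(chl$values) != length(poc$values)) {
    stop("alignment error: chlorophyll and POC series are not on the same",
         " daily grid")
  }
  # ug chl/l * (g C/g chl) = ug C/l; /1000 -> mg C/l
  phyto <- chl$values * c_to_chl / 1000
  det <- pmax(poc$values - phyto, 0)
  list(phyto_c = forcing_series("phyto_c", chl$start, phyto),
       det_zoo_c = forcing_series("det_zoo_c", chl$start, det))
}

#' Assemble a forcing bundle for one species
#'
#' @param species Species name.
#' @param series Named list of `forcing_series`, exactly those required by
#'   the species (see [forcing_requirements()]).
#' @param feed_composition Named numeric `c(protein=, lipid=, carbohydrate=)`
#'   for finfish (fractions summing to 1, constant over time); `NULL` for
#'   shellfish.
#' @return Object of class `forcing_bundle` (validated).
#' @export
forcing_bundle <- function(species, series, feed_composition = NULL) {
  species <- match_species(species)
  bundle <- structure(list(species = species, series = series,
                           feed_composition = feed_composition),
                      class = "forcing_bundle")
  validate_bundle(bundle)
}

#' Validate a forcing bundle against the species requirements
#'
#' Checks that exactly the series required by the species are present, that
#' all series share one daily grid, that concentration-type series are
#' non-negative, and (finfish) that the feed composition fractions are in
#' `[0, 1]` and sum to 1.
#'
#' @param bundle A `forcing_bundle`.
#' @return The bundle, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "forcing_bundle")) stop("not a forcing_bundle")
  species <- match_species(bundle$species)
  req <- forcing_requirements(species)
  have <- names(bundle$series)
  missing <- setdiff(req, have)
  extra <- setdiff(have, req)
  if (length(missing) || length(extra)) {
    stop("schema error for species '", species, "': ",
         if (length(missing)) paste0("missing series {",
                                     paste(missing, collapse = ", "), "} "),
         if (length(extra)) paste0("unexpected series {",
                                   paste(extra, collapse = ", "), "}"))
  }
  starts <- as.Date(vapply(bundle$series, function(s) as.character(s$start),
                           character(1)))
  lens <- vapply(bundle$series, function(s) length(s$values), integer(1))
  if (length(unique(starts)) != 1L || length(unique(lens)) != 1L) {
    stop("alignment error: forcing series do not share one daily grid")
  }
  for (s in bundle$series) {
    if (s$name %in% nonneg_forcings && any(s$values < 0)) {
      stop("series '", s$name, "' contains negative values")
    }
  }
  if (is_finfish(species)) {
    fc <- bundle$feed_composition
    need <- c("protein", "lipid", "carbohydrate")
    if (is.null(fc) || !all(need %in% names(fc))) {
      stop("schema error: finfish bundle needs feed_composition with ",
           "protein, lipid, carbohydrate fractions")
    }
    fc <- fc[need]
    if (any(fc < 0) || any(fc > 1) || abs(sum(fc) - 1) > 1e-8) {
      stop("feed composition fractions must lie in [0,1] and sum to 1")
    }
  } else if (!is.null(bundle$feed_composition)) {
    stop("shellfish bundles carry no feed composition")
  }
  invisible(bundle)
}

#' @export
print.forcing_bundle <- function(x, ...) {
  n <- length(x$series[[1]]$values)
  cat("<forcing_bundle:", x$species, "> ", n, " days from ",
      format(x$series[[1]]$start), "\n", sep = "")
  for (s in x$series) {
    cat(sprintf("  %-12s [%s] range %.4g..%.4g\n", s$name, s$units,
                min(s$values), max(s$values)))
  }
  if (!is.null(x$feed_composition)) {
    cat("  feed composition:",
        paste(sprintf("%s=%.2f", names(x$feed_composition),
                      x$feed_composition), collapse = " "), "\n")
  }
  invisible(x)
}

# Default seasonal cycles (Northern Adriatic-like conditions): mean,
# amplitude, calendar day of the annual maximum, and Gaussian noise SD.
default_seasonal_spec <- function(species) {
  base <- list(
    temperature = list(mean = 16, amplitude = 9, peak_doy = 220,
                       noise_sd = 0.5),
    chlorophyll = list(mean = 1.8, amplitude = 1.2, peak_doy = 105,
                       noise_sd = 0.3),
    poc = list(mean = 0.5, amplitude = 0.25, peak_doy = 105,
               noise_sd = 0.05),
    pom = list(mean = 1.2, amplitude = 0.5, peak_doy = 105, noise_sd = 0.1),
    tsm = list(mean = 6, amplitude = 3, peak_doy = 30, noise_sd = 1),
    poc_cp = list(mean = 106, amplitude = 0, peak_doy = 1, noise_sd = 0),
    poc_np = list(mean = 16, amplitude = 0, peak_doy = 1, noise_sd = 0),
    # feed schedule peaks in late summer and falls to ~0 at its late-winter
    # trough, approximating the seasonal feeding pause
    ration = if (species == "seabass") {
      list(mean = 1.5, amplitude = 1.5, peak_doy = 230, noise_sd = 0.2)
    } else {
      list(mean = 2.0, amplitude = 2.0, peak_doy = 230, noise_sd = 0.2)
    }
  )
  base[forcing_requirements(species)]
}

default_feed_composition <- function() {
  c(protein = 0.50, lipid = 0.22, carbohydrate = 0.28)
}

#' Generate a synthetic forcing bundle
#'
#' Builds daily forcing series as a sinusoidal annual cycle plus Gaussian
#' noise, clipped to physically admissible ranges (concentrations and
#' ration at zero from below; temperature is not clipped). The defaults
#' emulate Northern Adriatic coastal conditions. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param species Species name.
#' @param start First simulated day (`Date`).
#' @param n_days Number of days (>= 1).
#' @param seasonal_spec Optional named list overriding, per variable, any of
#'   `mean`, `amplitude`, `peak_doy`.
#' @param noise_sd Optional named numeric overriding the noise SD per
#'   variable.
#' @param seed Integer seed.
#' @param feed_composition Finfish feed composition (default 50/22/28
#'   protein/lipid/carbohydrate).
#' @return A validated `forcing_bundle`.
#' @export
generate_synthetic_forcings <- function(species, start, n_days,
                                        seasonal_spec = NULL,
                                        noise_sd = NULL, seed = 1,
                                        feed_composition = NULL) {
  species <- match_species(species)
  if (n_days < 1) stop("n_days must be >= 1")
  start <- as.Date(start)
  spec <- default_seasonal_spec(species)
  if (!is.null(seasonal_spec)) {
    for (nm in names(seasonal_spec)) {
      if (!nm %in% names(spec)) {
        stop("unknown forcing variable '", nm, "' for species ", species)
      }
      spec[[nm]] <- utils::modifyList(spec[[nm]], seasonal_spec[[nm]])
    }
  }
  if (!is.null(noise_sd)) {
    for (nm in names(noise_sd)) spec[[nm]]$noise_sd <- noise_sd[[nm]]
  }
  if (any(vapply(spec, function(s) s$amplitude < 0, logical(1)))) {
    stop("amplitudes must be >= 0")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  doy <- as.numeric(format(seq(start, by = "day", length.out = n_days),
                           "%j"))
  series <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    v <- s$mean + s$amplitude * cos(2 * pi * (doy - s$peak_doy) / 365.25)
    if (s$noise_sd > 0) v <- v + stats::rnorm(n_days, 0, s$noise_sd)
    if (nm %in% nonneg_forcings) v <- pmax(v, 0)
    series[[nm]] <- forcing_series(nm, start, v)
  }
  fc <- if (is_finfish(species)) {
    if (is.null(feed_composition)) default_feed_composition()
    else feed_composition
  } else NULL
  forcing_bundle(species, series, fc)
}

# Fast sub-daily lookup used by the RK4 solver: linear interpolation between
# daily values, except ration (a management variable) which is held constant
# over each day (zero-order hold).
forcing_interpolator <- function(series_list) {
  vals <- lapply(series_list, `[[`, "values")
  n <- length(vals[[1]])
  function(name, t) {
    v <- vals[[name]]
    if (name == "ration") {
      i <- min(floor(t), n - 1)
      return(v[i + 1])
    }
    if (t <= 0) return(v[1])
    if (t >= n - 1) return(v[n])
    i <- floor(t)
    f <- t - i
    v[i + 1] * (1 - f) + v[i + 2] * f
  }
}
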