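# Fixed-step classical Runge-Kutta integration of the daily energy balance
# and the individual-level simulation driver.

#' One classical fourth-order Runge-Kutta step
#'
#' Advances the state by one step of size `h` with the classical RK4
#' scheme. The derivative contract is `rhs(t, state) -> named numeric`
#' (same names as `state`). If an internal stage or the final state goes
#' negative it is clipped at zero with a warning (the empirical flux forms
#' can transiently undershoot near zero weight); non-finite derivatives
#' raise an error naming the day.
#'
#' @param rhs Function `(t, state) -> derivatives`.
#' @param state Named numeric state vector.
#' @param t Current time (days).
#' @param h Step size (days), > 0.
#' @return The state at `t + h`.
#' @export
rk4_step <- function(rhs, state, t, h) {
  if (h <= 0) stop("step size must be > 0")
  clip <- function(s) {
    if (any(s < 0)) {
      warning("state clipped at 0 during RK4 stage near day ", t,
              call. = FALSE)
      s <- pmax(s, 0)
    }
    s
  }
  check <- function(d) {
    if (any(!is.finite(d))) {
      stop("non-finite derivative at day ", t, " (state: ",
           paste(sprintf("%s=%.6g", names(state), state), collapse = ", "),
           ")")
    }
    d
  }
  k1 <- check(rhs(t, state))
  k2 <- check(rhs(t + h / 2, clip(state + h / 2 * k1)))
  k3 <- check(rhs(t + h / 2, clip(state + h / 2 * k2)))
  k4 <- check(rhs(t + h, clip(state + h * k3)))
  clip(state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

# initial states per species: Adriatic rearing-cycle seeding defaults
default_initial_state <- function(species) {
  switch(match_species(species),
         mussel = c(ws = 0.0333944, wg = 0),
         clam = c(w = 0.00702),
         seabass = c(w = 24),
         seabream = c(w = 80))
}

default_seed_day <- function(species) {
  switch(match_species(species),
         mussel = as.Date("2015-09-05"),
         clam = as.Date("2015-03-01"),
         seabass = as.Date("2015-05-15"),
         seabream = as.Date("2015-06-01"))
}

default_harvest_day <- function(species) {
  switch(match_species(species),
         mussel = as.Date("2016-07-05"),
         clam = as.Date("2016-06-15"),
         seabass = as.Date("2016-06-14"),
         seabream = as.Date("2016-05-01"))
}

# Build the derivative function and the daily flux evaluator for a species.
# `fi` is a forcing interpolator from forcing_interpolator(); for the mussel
# the derived food series (phytoplankton / detritus C) are pre-computed on
# the daily grid and interpolated linearly at sub-steps.
make_model <- function(species, params, bundle) {
  fi <- forcing_interpolator(bundle$series)
  if (species == "mussel") {
    food <- derive_mussel_food(bundle$series$chlorophyll, bundle$series$poc,
                               c_to_chl = pv(params, "c_to_chl"))
    fid <- forcing_interpolator(food)
    eval_fluxes <- function(t, state) {
      mussel_fluxes(state, fi("temperature", t),
                    list(phyto_c = fid("phyto_c", t),
                         det_zoo_c = fid("det_zoo_c", t),
                         pom = fi("pom", t), tsm = fi("tsm", t),
                         cp = fi("poc_cp", t), np = fi("poc_np", t)),
                    params)
    }
    rhs <- function(t, state) {
      fl <- eval_fluxes(t, state)
      c(ws = fl$d_soma_dt, wg = fl$d_gonad_dt)
    }
  } else if (species == "clam") {
    eval_fluxes <- function(t, state) {
      clam_fluxes(state, fi("temperature", t), fi("chlorophyll", t), params)
    }
    rhs <- function(t, state) {
      c(w = eval_fluxes(t, state)$dw_dt)
    }
  } else {
    fc <- bundle$feed_composition
    eval_fluxes <- function(t, state) {
      finfish_fluxes(state, fi("temperature", t), fi("ration", t), fc,
                     params)
    }
    rhs <- function(t, state) {
      c(w = eval_fluxes(t, state)$dw_dt)
    }
  }
  list(rhs = rhs, eval_fluxes = eval_fluxes)
}

#' Simulate one individual over a rearing cycle
#'
#' Steps the species energy balance with daily RK4 from seeding to harvest,
#' storing state, derived shell length (shellfish) and the daily flux
#' record. The mussel spawning event — an instantaneous release of the
#' gonad compartment, triggered when the gonad/soma ratio exceeds
#' `spawn_ratio` and the water is warmer than `t_spawn` — is applied
#' between daily steps and logged. Deterministic: no random numbers are
#' used.
#'
#' @param species Species name.
#' @param params `species_params` (default: the shipped set).
#' @param bundle Validated `forcing_bundle` covering
#'   `[seed_day, harvest_day]`.
#' @param seed_day,harvest_day Start and end of the rearing cycle
#'   (`Date`); defaults are typical Adriatic cycles per species.
#' @param initial_state Named state at seeding (default: typical seed
#'   weight per species).
#' @param overrides Named list of per-individual parameter overrides (e.g.
#'   `list(crmax = 52)` for a mussel, `list(imax = 0.1)` for a finfish).
#' @return Object of class `trajectory`: list with `species`, `days`
#'   (0-based index), `dates`, `state` (matrix day x state variable),
#'   `length` (shellfish; NULL otherwise), `flux` (matrix day x flux
#'   variable) and `events` (data frame of logged events).
#' @export
simulate_individual <- function(species, params = species_params(species),
                                bundle,
                                seed_day = default_seed_day(species),
                                harvest_day = default_harvest_day(species),
                                initial_state = default_initial_state(species),
                                overrides = list()) {
  species <- match_species(species)
  validate_bundle(bundle)
  if (bundle$species != species) stop("bundle species mismatch")
  seed_day <- as.Date(seed_day); harvest_day <- as.Date(harvest_day)
  if (harvest_day <= seed_day) stop("harvest_day must follow seed_day")

  b_start <- bundle$series[[1]]$start
  b_len <- length(bundle$series[[1]]$values)
  n <- as.integer(harvest_day - seed_day)      # number of daily steps
  off <- as.integer(seed_day - b_start)        # offset into the bundle grid
  if (off < 0 || off + n > b_len - 1) {
    stop("coverage error: bundle covers [", b_start, ", ",
         b_start + b_len - 1, "] but [", seed_day, ", ", harvest_day,
         "] was requested")
  }
  if (off > 0 || off + n < b_len - 1) {
    # restrict every series to the simulated window
    bundle$series <- lapply(bundle$series, function(s) {
      forcing_series(s$name, seed_day, s$values[(off + 1):(off + n + 1)],
                     s$units)
    })
  }

  # apply overrides on top of the supplied params (not the shipped file)
  if (length(overrides)) {
    p2 <- params
    for (nm in names(overrides)) {
      if (is.null(p2$params[[nm]])) {
        p2$params[[nm]] <- list(value = as.numeric(overrides[[nm]]),
                                units = "", description = "override")
      } else p2$params[[nm]]$value <- as.numeric(overrides[[nm]])
    }
    params <- p2
  }

  model <- make_model(species, params, bundle)
  state_names <- names(initial_state)
  states <- matrix(NA_real_, nrow = n + 1, ncol = length(initial_state),
                   dimnames = list(NULL, state_names))
  fnames <- flux_names(species)
  fluxes <- matrix(NA_real_, nrow = n + 1, ncol = length(fnames),
                   dimnames = list(NULL, fnames))
  events <- data.frame(day = integer(0), date = as.Date(character(0)),
                       event = character(0), detail = numeric(0))

  state <- initial_state
  spawnable <- species == "mussel"
  tvals <- bundle$series$temperature$values
  for (d in 0:n) {
    fl <- model$eval_fluxes(d, state)
    states[d + 1, ] <- state
    fluxes[d + 1, ] <- fl$flux[fnames]
    if (d < n) {
      state <- rk4_step(model$rhs, state, d, 1)
      if (spawnable) {
        Tnext <- tvals[d + 2]
        if (state[["ws"]] > 0 &&
            state[["wg"]] >= pv(params, "spawn_ratio") * state[["ws"]] &&
            Tnext >= pv(params, "t_spawn")) {
          events <- rbind(events, data.frame(
            day = d + 1L, date = seed_day + d + 1L, event = "spawning",
            detail = state[["wg"]]))
          state[["wg"]] <- 0
        }
      }
    }
  }

  len <- NULL
  if (!is_finfish(species)) {
    len <- apply(states, 1, shell_length, params = params)
  }
  structure(list(species = species, params = params,
                 days = 0:n, dates = seq(seed_day, harvest_day, by = "day"),
                 state = states, length = len, flux = fluxes,
                 events = events),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$days)
  cat("<trajectory:", x$species, "> ", n, " days (",
      format(x$dates[1]), " .. ", format(x$dates[n]), ")\n", sep = "")
  w0 <- x$state[1, ]; w1 <- x$state[n, ]
  cat("  state:", paste(sprintf("%s %.4g -> %.4g", colnames(x$state),
                                w0, w1), collapse = ", "), "\n")
  if (!is.null(x$length)) {
    cat(sprintf("  length: %.3g -> %.3g\n", x$length[1], x$length[n]))
  }
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@day%d", x$events$event,
                                   x$events$day), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Growth metric of a trajectory
#'
#' @param traj A `trajectory`.
#' @param metric `"length"` (shellfish) or `"weight"`.
#' @return Numeric vector, one value per day (total weight for the mussel).
#' @export
trajectory_metric <- function(traj, metric = c("length", "weight")) {
  metric <- match.arg(metric)
  if (metric == "length") {
    if (is.null(traj$length)) {
      stop("length metric unavailable for species '", traj$species, "'")
    }
    traj$length
  } else {
    rowSums(traj$state)
  }
}

#' Days needed to reach a commercial size
#'
#' Smallest day index (0 = seeding day) at which the growth metric reaches
#' the threshold; `NA` (the NOT-REACHED sentinel) if the size is never
#' attained within the trajectory.
#'
#' @param traj A `trajectory`.
#' @param threshold Size threshold (same units as the metric: cm for
#'   mussel length, mm for clam length, g for weight).
#' @param metric `"length"` or `"weight"`.
#' @return Integer day count, or `NA` if not reached.
#' @export
days_to_size <- function(traj, threshold, metric = c("length", "weight")) {
  m <- trajectory_metric(traj, match.arg(metric))
  hit <- which(m >= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(traj$days[hit[1]])
}

# default commercial-size thresholds (and metric) per species
default_thresholds <- function(species, params = species_params(species)) {
  switch(match_species(species),
         mussel = list(metric = "length",
                       thresholds = c(pv(params, "l_commercial"),
                                      pv(params, "l_target"))),
         clam = list(metric = "length",
                     thresholds = pv(params, "l_commercial")),
         seabass = ,
         seabream = list(metric = "weight",
                         thresholds = pv(params, "w_commercial")))
}
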