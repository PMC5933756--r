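# Monte Carlo up-scaling of the individual model to the farmed population
# and farm-level abundance dynamics.

#' Define a husbandry plan for a farmed population
#'
#' A plan fixes the rearing window, the stocking size, the natural
#' mortality rate, the Monte Carlo ensemble size and the between-individual
#' variability: every ensemble member receives an initial weight drawn from
#' a normal distribution and, depending on the species, an individual
#' maximum clearance rate (shellfish) or ingestion rate (finfish), also
#' normal. Draws are truncated at zero from below by redrawing.
#'
#' @param species Species name.
#' @param seed_day,harvest_day Rearing window (`Date`).
#' @param n_seeded Number of individuals stocked at seeding (> 0).
#' @param mortality_rate Natural mortality rate (1/d, >= 0); default from
#'   the species parameter set.
#' @param n_runs Monte Carlo ensemble size (>= 1).
#' @param initial_weight `c(mean, sd)` of the seeding weight (g; for the
#'   mussel, total dry weight).
#' @param rate_trait `c(mean, sd)` of the individual rate trait: `crmax`
#'   for shellfish, `imax` for finfish. Defaults to the parameter-set value
#'   with 20 percent relative SD.
#' @param seed Master RNG seed of the ensemble.
#' @return Object of class `husbandry_plan`.
#' @export
husbandry_plan <- function(species,
                           seed_day = default_seed_day(species),
                           harvest_day = default_harvest_day(species),
                           n_seeded,
                           mortality_rate = NULL,
                           n_runs = 5000,
                           initial_weight = NULL,
                           rate_trait = NULL,
                           seed = 1) {
  species <- match_species(species)
  params <- species_params(species)
  seed_day <- as.Date(seed_day); harvest_day <- as.Date(harvest_day)
  if (harvest_day <= seed_day) stop("harvest_day must follow seed_day")
  if (n_seeded <= 0) stop("n_seeded must be > 0")
  if (is.null(mortality_rate)) mortality_rate <- pv(params, "mortality")
  if (mortality_rate < 0) stop("mortality_rate must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  rate_symbol <- rate_trait_symbol(species)
  if (is.null(initial_weight)) {
    w0 <- sum(default_initial_state(species))
    initial_weight <- c(mean = w0, sd = 0.1 * w0)
  }
  if (is.null(rate_trait)) {
    r0 <- pv(params, rate_symbol)
    rate_trait <- c(mean = r0, sd = 0.2 * r0)
  }
  initial_weight <- stats::setNames(as.numeric(initial_weight),
                                    c("mean", "sd"))
  rate_trait <- stats::setNames(as.numeric(rate_trait), c("mean", "sd"))
  if (initial_weight["sd"] < 0 || rate_trait["sd"] < 0) {
    stop("trait SDs must be >= 0")
  }
  structure(list(species = species, seed_day = seed_day,
                 harvest_day = harvest_day, n_seeded = n_seeded,
                 mortality_rate = mortality_rate, n_runs = as.integer(n_runs),
                 initial_weight = initial_weight,
                 rate_trait = rate_trait, rate_symbol = rate_symbol,
                 seed = as.integer(seed)),
            class = "husbandry_plan")
}

#' @export
print.husbandry_plan <- function(x, ...) {
  cat("<husbandry_plan:", x$species, "> ", format(x$seed_day), " .. ",
      format(x$harvest_day), "\n", sep = "")
  cat(sprintf("  seeded %d ind, mortality %.5f /d, %d Monte Carlo runs\n",
              x$n_seeded, x$mortality_rate, x$n_runs))
  cat(sprintf("  initial weight %.4g +/- %.4g g, %s %.4g +/- %.4g\n",
              x$initial_weight["mean"], x$initial_weight["sd"],
              x$rate_symbol, x$rate_trait["mean"], x$rate_trait["sd"]))
  invisible(x)
}

# per-individual rate trait varied in the Monte Carlo ensemble: ingestion
# rate for finfish, maximum clearance rate for the mussel; the clam model
# has no clearance term, so its food-uptake coefficient is varied instead
rate_trait_symbol <- function(species) {
  switch(match_species(species),
         seabass = , seabream = "imax",
         mussel = "crmax",
         clam = "a_ana")
}

# normal draw truncated at zero from below by redraw
rnorm_pos <- function(n, mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw the Monte Carlo cohort of a husbandry plan
#'
#' Draws `n_runs` individuals: an initial state and a per-individual
#' parameter override per member. All traits are drawn up front from one
#' seeded RNG stream, so results do not depend on the order in which the
#' ensemble is later executed. The caller's RNG state is left untouched.
#'
#' @param plan A `husbandry_plan`.
#' @return List of length `n_runs`; each element is
#'   `list(initial_state, overrides)`.
#' @export
draw_cohort <- function(plan) {
  stopifnot(inherits(plan, "husbandry_plan"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(plan$seed)
  w0 <- rnorm_pos(plan$n_runs, plan$initial_weight["mean"],
                  plan$initial_weight["sd"])
  r0 <- rnorm_pos(plan$n_runs, plan$rate_trait["mean"],
                  plan$rate_trait["sd"])
  lapply(seq_len(plan$n_runs), function(i) {
    st <- if (plan$species == "mussel") c(ws = w0[i], wg = 0)
          else c(w = w0[i])
    list(initial_state = st,
         overrides = stats::setNames(list(r0[i]), plan$rate_symbol))
  })
}

#' Farm abundance under constant natural mortality
#'
#' Between husbandry events the number of individuals decays as
#' `N(t) = n_seeded * exp(-mortality_rate * t)`; stocking and harvesting
#' enter as step discontinuities (the default plan stocks once at day 0
#' and harvests everything at the end of the window).
#'
#' @param plan A `husbandry_plan`.
#' @param t Day index (0 = seeding day), within the rearing window;
#'   vectorized.
#' @return Real-valued abundance at each `t`.
#' @export
abundance <- function(plan, t) {
  stopifnot(inherits(plan, "husbandry_plan"))
  horizon <- as.integer(plan$harvest_day - plan$seed_day)
  if (any(t < 0 | t > horizon)) {
    stop("day index outside the rearing window [0, ", horizon, "]")
  }
  plan$n_seeded * exp(-plan$mortality_rate * t)
}

#' Run the Monte Carlo population simulation
#'
#' Simulates every cohort member with [simulate_individual()], then
#' computes, for every state/length/flux variable, the per-day ensemble
#' mean and sample standard deviation (n - 1 denominator), the abundance
#' time series, the farm-level fluxes (per-capita ensemble mean times
#' abundance, converted to kg/d — kg N/d for NH4), and the distribution of
#' days-to-commercial-size across the ensemble. Ensemble members are
#' independent and all randomness is drawn up front, so results are
#' invariant to execution order.
#'
#' @param species Species name.
#' @param params `species_params` (default: shipped set).
#' @param bundle Validated `forcing_bundle` covering the plan window.
#' @param plan A `husbandry_plan` for the same species.
#' @param thresholds Optional commercial-size thresholds (default: species
#'   standard, e.g. 5 and 7 cm for the mussel).
#' @return Object of class `population_result`: list with `plan`, `days`,
#'   `dates`, `abundance`, `mean` and `sd` (day x variable matrices),
#'   `farm_flux` (kg/d, day x mass-flux variable), `days_to_size` (matrix
#'   individuals x thresholds), `harvested_nominal` (the plan's bookkeeping
#'   figure) and `harvested_model` (N at harvest from the mortality law).
#' @export
run_population <- function(species, params = species_params(species),
                           bundle, plan, thresholds = NULL) {
  species <- match_species(species)
  stopifnot(inherits(plan, "husbandry_plan"), plan$species == species)
  validate_bundle(bundle)
  cohort <- draw_cohort(plan)

  thr <- default_thresholds(species, params)
  if (!is.null(thresholds)) thr$thresholds <- thresholds

  trajs <- lapply(seq_along(cohort), function(i) {
    member <- cohort[[i]]
    tryCatch(
      simulate_individual(species, params, bundle,
                          seed_day = plan$seed_day,
                          harvest_day = plan$harvest_day,
                          initial_state = member$initial_state,
                          overrides = member$overrides),
      error = function(e) stop("ensemble run ", i, " failed: ",
                               conditionMessage(e)))
  })

  n_days <- length(trajs[[1]]$days)
  # assemble day x variable x individual array
  var_of <- function(traj) {
    m <- cbind(traj$state, traj$flux)
    if (!is.null(traj$length)) m <- cbind(m, length = traj$length)
    m
  }
  v1 <- var_of(trajs[[1]])
  arr <- vapply(trajs, var_of, v1)
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- if (length(trajs) > 1) apply(arr, c(1, 2), stats::sd)
          else matrix(0, nrow(v1), ncol(v1), dimnames = dimnames(v1))
  dimnames(mean_m) <- dimnames(sd_m) <- dimnames(v1)

  days <- trajs[[1]]$days
  N <- abundance(plan, days)

  # farm-level mass fluxes: mean per-capita g/d * N / 1000 -> kg/d
  mass_flux <- intersect(colnames(trajs[[1]]$flux), c(
    "ingestion", "uneaten_protein", "uneaten_lipid", "uneaten_carb",
    "faeces_protein", "faeces_lipid", "faeces_carb",
    "filtered_c", "ingested_c",
    "pseudofaeces_c", "pseudofaeces_n", "pseudofaeces_p",
    "faeces_c", "faeces_n", "faeces_p",
    "o2_consumption", "nh4_excretion"))
  farm <- if (length(mass_flux)) {
    sweep(mean_m[, mass_flux, drop = FALSE], 1, N, `*`) / 1000
  } else NULL

  dts <- vapply(trajs, function(tr) {
    vapply(thr$thresholds, function(x) days_to_size(tr, x, thr$metric),
           integer(1))
  }, integer(length(thr$thresholds)))
  dts <- matrix(t(dts), nrow = length(trajs),
                dimnames = list(NULL, paste0("threshold_", thr$thresholds)))

  structure(list(plan = plan, days = days,
                 dates = trajs[[1]]$dates, abundance = N,
                 mean = mean_m, sd = sd_m, farm_flux = farm,
                 days_to_size = dts,
                 size_metric = thr$metric, thresholds = thr$thresholds,
                 harvested_nominal = plan$n_seeded,
                 harvested_model = N[length(N)]),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  n <- length(x$days)
  cat("<population_result:", x$plan$species, "> ", x$plan$n_runs,
      " runs, ", n, " days\n", sep = "")
  cat(sprintf("  abundance %d -> %.0f (nominal harvest %d)\n",
              x$plan$n_seeded, x$harvested_model, x$harvested_nominal))
  w <- if ("w" %in% colnames(x$mean)) "w" else "ws"
  cat(sprintf("  mean %s: %.4g -> %.4g g (final SD %.3g)\n", w,
              x$mean[1, w], x$mean[n, w], x$sd[n, w]))
  reached <- colMeans(!is.na(x$days_to_size)) * 100
  cat("  reached size:", paste(sprintf("%s %.1f%%",
      colnames(x$days_to_size), reached), collapse = ", "), "\n")
  invisible(x)
}
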