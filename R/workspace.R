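# User-facing workflow: create a workspace with template inputs, load and
# validate them, run the model, and persist tables, plots and a log.

AQ_LEVELS <- c("ind", "pop")

match_level <- function(level) match.arg(tolower(level), AQ_LEVELS)

ws_dir <- function(root, species, level) {
  file.path(root, paste(species, level, sep = "_"))
}

# Table of output variables per species/level: state variables, length,
# flux columns, days-to-size summary; population runs add abundance.
output_variables <- function(species, level) {
  species <- match_species(species)
  level <- match_level(level)
  states <- names(default_initial_state(species))
  vars <- c(states,
            if (!is_finfish(species)) "length",
            flux_names(species))
  if (level == "pop") vars <- c(vars, "abundance")
  vars
}

#' Create a model workspace with template inputs
#'
#' Builds the folder tree for one species/level combination under `root`
#' and writes ready-to-run template files: forcing CSVs from the synthetic
#' generator (fixed seed, typical Adriatic seasonal cycles), a copy of the
#' species parameter table, and a YAML configuration with the default
#' rearing cycle and (population level) husbandry plan. Re-running the
#' function overwrites all template files.
#'
#' @param root Workspace root path (created if absent).
#' @param species Species name.
#' @param level `"ind"` (individual) or `"pop"` (population).
#' @param seed Seed of the synthetic template forcings.
#' @return The workspace directory path, invisibly.
#' @export
create_skeleton <- function(root, species, level, seed = 42) {
  species <- match_species(species)
  level <- match_level(level)
  base <- ws_dir(root, species, level)
  dirs <- file.path(base, c("inputs/forcings", "inputs/params",
                            "inputs/config", "outputs/tables",
                            "outputs/plots"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  seed_day <- default_seed_day(species)
  harvest_day <- default_harvest_day(species)
  # template forcings start before seeding and end after harvest so the
  # daily interpolation window is always covered
  f_start <- seed_day - 5
  n_days <- as.integer(harvest_day - seed_day) + 11L
  bundle <- generate_synthetic_forcings(species, f_start, n_days,
                                        seed = seed)
  for (s in bundle$series) {
    raw <- raw_series(s$name, seq(s$start, by = "day",
                                  length.out = length(s$values)),
                      s$values, s$units)
    write_forcing_table(raw, file.path(base, "inputs/forcings",
                                       paste0(species, "_", s$name, ".csv")))
  }
  file.copy(system.file("extdata", paste0("params_", species, ".csv"),
                        package = "aquafarm", mustWork = TRUE),
            file.path(base, "inputs/params", "params.csv"),
            overwrite = TRUE)

  cfg <- list(
    species = species, level = level,
    seed_day = format(seed_day, "%Y-%m-%d"),
    harvest_day = format(harvest_day, "%Y-%m-%d"),
    initial_state = as.list(default_initial_state(species)),
    seed = seed)
  if (is_finfish(species)) {
    cfg$feed_composition <- as.list(default_feed_composition())
  }
  if (level == "pop") {
    params <- species_params(species)
    w0 <- sum(default_initial_state(species))
    rate_symbol <- rate_trait_symbol(species)
    cfg$husbandry <- list(
      n_seeded = if (species == "seabream") 52988L else 10000L,
      mortality_rate = pv(params, "mortality"),
      n_runs = 5000L,
      initial_weight = list(mean = w0, sd = 0.1 * w0),
      rate_trait = list(mean = pv(params, rate_symbol),
                        sd = 0.2 * pv(params, rate_symbol)))
  }
  yaml::write_yaml(cfg, file.path(base, "inputs/config", "config.yaml"))
  invisible(base)
}

#' Load and validate a workspace
#'
#' Reads the forcing CSVs, interpolates them onto the daily grid of the
#' configured rearing window, derives the mussel food pools, validates the
#' bundle, loads the parameter table and the configuration, and saves one
#' plot of each interpolated forcing under `outputs/plots`.
#'
#' @param root Workspace root path.
#' @param species Species name.
#' @param level `"ind"` or `"pop"`.
#' @return List with `bundle` (validated `forcing_bundle`), `params`
#'   (`species_params`), `config` (parsed YAML) and, at population level,
#'   `plan` (`husbandry_plan`).
#' @export
load_workspace <- function(root, species, level) {
  species <- match_species(species)
  level <- match_level(level)
  base <- ws_dir(root, species, level)
  if (!dir.exists(base)) {
    stop("no workspace for ", species, "_", level, " under ", root,
         "; run create_skeleton() first")
  }
  cfg <- yaml::read_yaml(file.path(base, "inputs/config", "config.yaml"))
  seed_day <- as.Date(cfg$seed_day)
  harvest_day <- as.Date(cfg$harvest_day)

  series <- list()
  for (nm in forcing_requirements(species)) {
    f <- file.path(base, "inputs/forcings",
                   paste0(species, "_", nm, ".csv"))
    if (!file.exists(f)) stop("schema error: missing forcing file ", f)
    raw <- tryCatch(read_forcing_table(f, nm),
                    error = function(e) {
                      stop("in file ", f, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    series[[nm]] <- interpolate_daily(raw, seed_day, harvest_day)
  }
  fc <- if (is_finfish(species)) {
    unlist(cfg$feed_composition)[c("protein", "lipid", "carbohydrate")]
  } else NULL
  bundle <- forcing_bundle(species, series, fc)
  params <- species_params(species,
                           file = file.path(base, "inputs/params",
                                            "params.csv"))

  plot_dir <- file.path(base, "outputs/plots")
  for (s in bundle$series) {
    grDevices::png(file.path(plot_dir, paste0("forcing_", s$name, ".png")),
                   width = 800, height = 500)
    graphics::plot(seq(s$start, by = "day", length.out = length(s$values)),
                   s$values, type = "l",
                   xlab = "date", ylab = paste0(s$name, " [", s$units, "]"),
                   main = paste("Interpolated forcing:", s$name))
    grDevices::dev.off()
  }

  out <- list(bundle = bundle, params = params, config = cfg)
  if (level == "pop") {
    h <- cfg$husbandry
    out$plan <- husbandry_plan(
      species, seed_day = seed_day, harvest_day = harvest_day,
      n_seeded = h$n_seeded, mortality_rate = h$mortality_rate,
      n_runs = h$n_runs,
      initial_weight = c(h$initial_weight$mean, h$initial_weight$sd),
      rate_trait = c(h$rate_trait$mean, h$rate_trait$sd),
      seed = if (!is.null(cfg$seed)) cfg$seed else 1)
  }
  out
}

fmt_num <- function(x) format(x, digits = 15, trim = TRUE,
                              scientific = FALSE)

write_units_csv <- function(tab, units, path) {
  # header row of units below the column names, then data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  for (i in seq_len(nrow(tab))) {
    row <- vapply(tab[i, ], function(v) {
      if (is.na(v)) "" else if (is.numeric(v)) fmt_num(v) else as.character(v)
    }, character(1))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

state_units <- function(species) {
  switch(match_species(species),
         mussel = c(ws = "g dry", wg = "g dry"),
         clam = c(w = "g"),
         seabass = , seabream = c(w = "g"))
}

length_units <- function(species) {
  if (species == "mussel") "cm" else "mm"
}

write_trajectory <- function(traj, dir) {
  sp <- traj$species
  st <- as.data.frame(traj$state)
  su <- state_units(sp)
  tab <- data.frame(day = traj$days, date = format(traj$dates, "%Y-%m-%d"))
  un <- c(day = "d", date = "ISO-8601")
  tab <- cbind(tab, st)
  un <- c(un, su)
  if (!is.null(traj$length)) {
    tab$length <- traj$length
    un <- c(un, length = length_units(sp))
  }
  write_units_csv(tab, un, file.path(dir, "states.csv"))

  fx <- as.data.frame(traj$flux)
  ftab <- cbind(data.frame(day = traj$days,
                           date = format(traj$dates, "%Y-%m-%d")), fx)
  fun <- c(day = "d", date = "ISO-8601", flux_units_map(sp))
  write_units_csv(ftab, fun, file.path(dir, "fluxes.csv"))

  if (nrow(traj$events)) {
    utils::write.csv(traj$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

write_population <- function(res, dir) {
  sp <- res$plan$species
  base <- data.frame(day = res$days, date = format(res$dates, "%Y-%m-%d"))
  vu <- c(state_units(sp), flux_units_map(sp))
  if (!is_finfish(sp)) vu <- c(vu, length = length_units(sp))
  un <- c(day = "d", date = "ISO-8601", vu[colnames(res$mean)])
  write_units_csv(cbind(base, as.data.frame(res$mean)), un,
                  file.path(dir, "mean.csv"))
  write_units_csv(cbind(base, as.data.frame(res$sd)), un,
                  file.path(dir, "sd.csv"))
  write_units_csv(cbind(base, abundance = res$abundance),
                  c(day = "d", date = "ISO-8601", abundance = "ind"),
                  file.path(dir, "abundance.csv"))
  if (!is.null(res$farm_flux)) {
    fu <- rep("kg/d", ncol(res$farm_flux))
    fu[colnames(res$farm_flux) == "nh4_excretion"] <- "kgN/d"
    write_units_csv(cbind(base, as.data.frame(res$farm_flux)),
                    c(day = "d", date = "ISO-8601", fu),
                    file.path(dir, "farm_fluxes.csv"))
  }
  utils::write.csv(as.data.frame(res$days_to_size),
                   file.path(dir, "days_to_size.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

run_plots <- function(species, level, obj, dir) {
  png1 <- function(name, expr) {
    grDevices::png(file.path(dir, paste0(name, ".png")),
                   width = 800, height = 500)
    on.exit(grDevices::dev.off())
    expr()
  }
  if (level == "ind") {
    png1("growth", function() {
      graphics::plot(obj$dates, rowSums(obj$state), type = "l",
                     xlab = "date", ylab = "weight [g]",
                     main = paste(species, "individual growth"))
    })
    if (!is.null(obj$length)) {
      png1("length", function() {
        graphics::plot(obj$dates, obj$length, type = "l", xlab = "date",
                       ylab = paste0("length [", length_units(species), "]"),
                       main = paste(species, "shell length"))
      })
    }
    png1("metabolism", function() {
      graphics::matplot(obj$dates, obj$flux[, c("anabolism", "catabolism")],
                        type = "l", lty = 1, col = c("blue", "red"),
                        xlab = "date", ylab = "rate [J/d]",
                        main = "Anabolic and catabolic rates")
      graphics::legend("topleft", c("anabolism", "catabolism"),
                       col = c("blue", "red"), lty = 1)
    })
    tf <- grep("^tfun_", colnames(obj$flux), value = TRUE)
    png1("temperature_response", function() {
      graphics::matplot(obj$dates, obj$flux[, tf], type = "l", lty = 1,
                        xlab = "date", ylab = "response [-]",
                        main = "Temperature response functions")
      graphics::legend("topleft", tf, lty = 1,
                       col = seq_along(tf))
    })
    wst <- intersect(colnames(obj$flux),
                     c("faeces_protein", "faeces_lipid", "faeces_carb",
                       "uneaten_protein", "uneaten_lipid", "uneaten_carb",
                       "faeces_c", "pseudofaeces_c"))
    if (length(wst)) {
      png1("waste", function() {
        graphics::matplot(obj$dates, obj$flux[, wst], type = "l", lty = 1,
                          xlab = "date", ylab = "flux [g/d]",
                          main = "Organic waste production")
        graphics::legend("topleft", wst, lty = 1, col = seq_along(wst))
      })
    }
  } else {
    wname <- if (species == "mussel") "ws" else "w"
    png1("growth", function() {
      m <- obj$mean[, wname]; s <- obj$sd[, wname]
      graphics::plot(obj$dates, m, type = "l", ylim = range(m - s, m + s),
                     xlab = "date", ylab = "mean weight [g]",
                     main = paste(species, "population growth (mean +/- SD)"))
      graphics::lines(obj$dates, m + s, lty = 2)
      graphics::lines(obj$dates, m - s, lty = 2)
    })
    png1("abundance", function() {
      graphics::plot(obj$dates, obj$abundance, type = "l", xlab = "date",
                     ylab = "individuals", main = "Farm abundance")
    })
    if (!is.null(obj$farm_flux)) {
      wst <- intersect(colnames(obj$farm_flux),
                       c("faeces_protein", "faeces_lipid", "faeces_carb",
                         "faeces_c", "pseudofaeces_c"))
      if (length(wst)) {
        png1("farm_waste", function() {
          graphics::matplot(obj$dates, obj$farm_flux[, wst], type = "l",
                            lty = 1, xlab = "date", ylab = "flux [kg/d]",
                            main = "Farm-level organic waste")
          graphics::legend("topleft", wst, lty = 1, col = seq_along(wst))
        })
      }
    }
  }
  invisible(dir)
}

#' Run a loaded workspace and persist all outputs
#'
#' Loads the workspace (see [load_workspace()]), runs the individual or
#' population model, and writes the numerical outputs (CSV tables with
#' units in the header), the standard plots, a days-to-commercial-size
#' summary, and a plain-text log echoing the configuration and the seed.
#' With a fixed seed the run is byte-reproducible.
#'
#' @param root Workspace root path.
#' @param species Species name.
#' @param level `"ind"` or `"pop"`.
#' @param seed Optional RNG seed overriding the configured one
#'   (population level).
#' @return Invisibly, the model result (`trajectory` or
#'   `population_result`).
#' @export
run_main <- function(root, species, level, seed = NULL) {
  species <- match_species(species)
  level <- match_level(level)
  ws <- load_workspace(root, species, level)
  base <- ws_dir(root, species, level)
  tdir <- file.path(base, "outputs/tables")
  pdir <- file.path(base, "outputs/plots")
  cfg <- ws$config
  seed_day <- as.Date(cfg$seed_day)
  harvest_day <- as.Date(cfg$harvest_day)

  if (level == "ind") {
    res <- simulate_individual(species, ws$params, ws$bundle,
                               seed_day = seed_day,
                               harvest_day = harvest_day,
                               initial_state = unlist(cfg$initial_state))
    write_trajectory(res, tdir)
    thr <- default_thresholds(species, ws$params)
    dts <- vapply(thr$thresholds, function(x) {
      as.numeric(days_to_size(res, x, thr$metric))
    }, numeric(1))
    utils::write.csv(
      data.frame(metric = thr$metric, threshold = thr$thresholds,
                 days = dts),
      file.path(tdir, "days_to_size.csv"), row.names = FALSE, na = "")
  } else {
    plan <- ws$plan
    if (!is.null(seed)) plan$seed <- as.integer(seed)
    res <- run_population(species, ws$params, ws$bundle, plan)
    write_population(res, tdir)
  }
  run_plots(species, level, res, pdir)

  log_lines <- c(
    paste0("aquafarm run ", species, "_", level),
    paste0("package version: ",
           as.character(utils::packageVersion("aquafarm"))),
    paste0("seed_day: ", format(seed_day)),
    paste0("harvest_day: ", format(harvest_day)),
    paste0("seed: ", if (level == "pop") {
      if (!is.null(seed)) seed else cfg$seed
    } else "none (deterministic)"),
    paste0("config: ", gsub("\n", " | ", yaml::as.yaml(cfg))))
  writeLines(log_lines, file.path(base, "outputs", "run.log"))
  invisible(res)
}
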