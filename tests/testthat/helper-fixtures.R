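# Shared fixture builders: constant-forcing bundles and quick synthetic
# bundles spanning a species' default rearing window.

constant_bundle <- function(species, n_days, start = "2015-06-01",
                            temperature = 20, chlorophyll = 2, poc = 0.5,
                            pom = 1.2, tsm = 6, poc_cp = 106, poc_np = 16,
                            ration = 2,
                            feed = c(protein = 0.5, lipid = 0.22,
                                     carbohydrate = 0.28)) {
  vals <- list(temperature = temperature, chlorophyll = chlorophyll,
               poc = poc, pom = pom, tsm = tsm, poc_cp = poc_cp,
               poc_np = poc_np, ration = ration)
  series <- lapply(forcing_requirements(species), function(nm) {
    forcing_series(nm, as.Date(start), rep(vals[[nm]], n_days))
  })
  names(series) <- forcing_requirements(species)
  fc <- if (species %in% c("seabass", "seabream")) feed else NULL
  forcing_bundle(species, series, fc)
}

# synthetic bundle covering the default rearing window plus margins
window_bundle <- function(species, seed = 7, seasonal_spec = NULL) {
  sd0 <- aquafarm:::default_seed_day(species)
  hd <- aquafarm:::default_harvest_day(species)
  generate_synthetic_forcings(species, sd0 - 3, as.integer(hd - sd0) + 7,
                              seasonal_spec = seasonal_spec, seed = seed)
}

# minimal hand-built trajectory for days_to_size tests
fake_trajectory <- function(days, length = NULL, weight = NULL) {
  structure(list(species = if (is.null(length)) "seabream" else "mussel",
                 days = days,
                 state = matrix(if (is.null(weight)) 0 * days else weight,
                                ncol = 1, dimnames = list(NULL, "w")),
                 length = length),
            class = "trajectory")
}
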