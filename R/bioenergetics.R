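# Species-specific instantaneous flux equations: temperature responses,
# anabolism, catabolism, ingestion, organic wastes and metabolite
# by-products. All rates are per individual and per day; the energy balance
# is dw/dt = (A - C)/eps with A, C in J d^-1 and eps in J g^-1.

# admissible temperature range of the empirical formulations
T_RANGE <- c(-2, 40)

check_temperature <- function(T) {
  if (!is.finite(T) || T < T_RANGE[1] || T > T_RANGE[2]) {
    stop("temperature ", T, " degC outside admissible range [",
         T_RANGE[1], ", ", T_RANGE[2], "] degC")
  }
  invisible(T)
}

# (species, process) -> functional form and its parameter symbols
tresp_registry <- function(species, process) {
  key <- paste(species, process, sep = ".")
  forms <- list(
    seabream.anabolism  = list(form = "gaussian", topt = "topt_ana", tsig = "tsig_ana"),
    seabream.catabolism = list(form = "q10exp", pc = "pc_cat", tref = "tref_cat"),
    seabass.anabolism   = list(form = "gaussian", topt = "topt_ana", tsig = "tsig_ana"),
    seabass.catabolism  = list(form = "q10exp", pc = "pc_cat", tref = "tref_cat"),
    mussel.filtration   = list(form = "gaussian", topt = "topt_filt", tsig = "tsig_filt"),
    mussel.catabolism   = list(form = "q10exp", pc = "pc_cat", tref = "tref_cat"),
    clam.anabolism      = list(form = "gaussian", topt = "topt_ana", tsig = "tsig_ana"),
    clam.catabolism     = list(form = "q10exp", pc = "pc_cat", tref = "tref_cat")
  )
  f <- forms[[key]]
  if (is.null(f)) {
    stop("no temperature response defined for species '", species,
         "', process '", process, "'")
  }
  f
}

#' Temperature response function
#'
#' Dimensionless temperature limitation/stimulation factor of a metabolic
#' process. Two functional forms are used: a Gaussian optimum curve
#' `exp(-((T - Topt)/sigma)^2)` (equals 1 at the optimum) for anabolic and
#' filtration processes, and a normalized exponential
#' `exp(p (T - Tref))` (equals 1 at the reference temperature) for
#' catabolic processes. Temperatures outside the admissible range
#' `[-2, 40]` degC raise an error: the empirical forms are not trusted
#' outside their calibration range.
#'
#' @param T Water temperature (degC).
#' @param params A `species_params` object.
#' @param process One of `"anabolism"`, `"catabolism"` (all species) or
#'   `"filtration"` (mussel).
#' @return Finite non-negative scalar.
#' @export
temperature_response <- function(T, params, process) {
  stopifnot(inherits(params, "species_params"))
  check_temperature(T)
  f <- tresp_registry(params$species, process)
  switch(f$form,
    gaussian = exp(-((T - pv(params, f$topt)) / pv(params, f$tsig))^2),
    q10exp = exp(pv(params, f$pc) * (T - pv(params, f$tref))))
}

#' Validate a finfish feed composition
#'
#' @param protein,lipid,carbohydrate Mass fractions of the feed, summing
#'   to 1.
#' @return Named numeric vector `c(protein, lipid, carbohydrate)`.
#' @export
feed_composition <- function(protein, lipid, carbohydrate) {
  fc <- c(protein = protein, lipid = lipid, carbohydrate = carbohydrate)
  if (any(fc < 0) || abs(sum(fc) - 1) > 1e-8) {
    stop("feed composition fractions must be >= 0 and sum to 1")
  }
  fc
}

finfish_flux_names <- c(
  "anabolism", "catabolism", "ingestion",
  "uneaten_protein", "uneaten_lipid", "uneaten_carb",
  "faeces_protein", "faeces_lipid", "faeces_carb",
  "o2_consumption", "nh4_excretion",
  "tfun_anabolism", "tfun_catabolism")

mussel_flux_names <- c(
  "anabolism", "catabolism", "filtered_c", "ingested_c",
  "pseudofaeces_c", "pseudofaeces_n", "pseudofaeces_p",
  "faeces_c", "faeces_n", "faeces_p",
  "o2_consumption", "nh4_excretion",
  "tfun_filtration", "tfun_catabolism",
  "tissue_c", "tissue_n", "tissue_p")

clam_flux_names <- c("anabolism", "catabolism",
                     "tfun_anabolism", "tfun_catabolism")

flux_names <- function(species) {
  switch(match_species(species),
         seabream = , seabass = finfish_flux_names,
         mussel = mussel_flux_names,
         clam = clam_flux_names)
}

#' Daily flux balance of a finfish individual (seabream or seabass)
#'
#' Potential ingestion is `imax * Tfun_A(T) * w^m` (g feed per day) and the
#' realized ingestion is capped by the supplied ration. The uneaten ration
#' and the faeces are split by macronutrient class (protein/lipid/
#' carbohydrate): `faeces_k = ingested_k * (1 - digestibility_k)`. The
#' anabolic rate is the digested energy times the net anabolic efficiency
#' `alpha_ana`; the catabolic rate is `k_cat * Tfun_C(T) * w^n_cat`. Oxygen
#' consumption and ammonia excretion follow from the catabolic rate via
#' [metabolic_byproducts()].
#'
#' @param state Named numeric with element `w`, wet weight (g), > 0.
#' @param T Water temperature (degC).
#' @param ration Feed offered (g per individual per day), >= 0.
#' @param feed Feed composition (see [feed_composition()]).
#' @param params `species_params` for `"seabream"` or `"seabass"`.
#' @return List with `dw_dt` (g/d) and `flux`, a named numeric holding the
#'   daily flux record (J/d for energies, g/d for masses, gN/d for NH4).
#' @export
finfish_fluxes <- function(state, T, ration, feed, params) {
  stopifnot(inherits(params, "species_params"),
            is_finfish(params$species))
  w <- unname(state[["w"]])
  if (!is.finite(w) || w <= 0) stop("non-positive finfish weight")
  if (ration < 0) stop("ration must be >= 0")
  fc <- feed[c("protein", "lipid", "carbohydrate")]

  tf_a <- temperature_response(T, params, "anabolism")
  tf_c <- temperature_response(T, params, "catabolism")

  ing_pot <- pv(params, "imax") * tf_a * w^pv(params, "m")
  ing <- min(ing_pot, ration)
  uneaten <- ration - ing

  dig <- c(protein = pv(params, "dig_protein"),
           lipid = pv(params, "dig_lipid"),
           carb = pv(params, "dig_carb"))
  en <- c(protein = pv(params, "en_protein"),
          lipid = pv(params, "en_lipid"),
          carb = pv(params, "en_carb"))
  ing_k <- ing * fc
  un_k <- uneaten * fc
  faeces_k <- ing_k * (1 - dig)
  digested_energy <- sum(ing_k * dig * en)

  A <- pv(params, "alpha_ana") * digested_energy
  C <- pv(params, "k_cat") * tf_c * w^pv(params, "n_cat")
  dw_dt <- (A - C) / pv(params, "eps")

  flux <- c(anabolism = A, catabolism = C, ingestion = ing,
            uneaten_protein = unname(un_k["protein"]),
            uneaten_lipid = unname(un_k["lipid"]),
            uneaten_carb = unname(un_k["carbohydrate"]),
            faeces_protein = unname(faeces_k["protein"]),
            faeces_lipid = unname(faeces_k["lipid"]),
            faeces_carb = unname(faeces_k["carbohydrate"]),
            o2_consumption = 0, nh4_excretion = 0,
            tfun_anabolism = tf_a, tfun_catabolism = tf_c)
  by <- metabolic_byproducts(flux, params)
  flux["o2_consumption"] <- by$O2
  flux["nh4_excretion"] <- by$NH4
  list(dw_dt = dw_dt, flux = flux)
}

#' Daily flux balance of a mussel individual
#'
#' Filtration clears water at `crmax * Tfun_f(T) * wd^b_cr` litres per day
#' (`wd` = total dry weight) over the available organic carbon
#' (phytoplankton plus detritus + zooplankton). When the filtered carbon
#' exceeds the ingestion capacity `ing_cap * wd^b_cr` the surplus is
#' rejected as pseudofaeces; otherwise all filtered material is ingested.
#' Ingested carbon is absorbed with pool-specific efficiencies
#' (phytoplankton `ae_phyto`, detritus `ae_det`); the remainder is egested
#' as faeces. The anabolic rate is absorbed carbon times the food energy
#' content `en_food`; catabolism scales on somatic dry weight. Positive net
#' production is split between soma and gonad (`gonad_frac` to gonad) once
#' the animal is mature (`l_mat`) and water is warmer than `t_gam`; the
#' spawning event itself is handled by [simulate_individual()]. Faeces and
#' pseudofaeces carbon is converted to N and P through the POC C/P and N/P
#' molar ratios.
#'
#' @param state Named numeric with `ws` (somatic dry weight, g) and `wg`
#'   (gonadic dry weight, g), both >= 0.
#' @param T Water temperature (degC).
#' @param food Named list/vector with `phyto_c`, `det_zoo_c` (mgC/l),
#'   `pom`, `tsm` (mg/l), `cp` (mol C / mol P), `np` (mol N / mol P);
#'   all >= 0.
#' @param params `species_params` for `"mussel"`.
#' @return List with `d_soma_dt`, `d_gonad_dt` (g dry weight/d) and `flux`
#'   (named numeric; energies J/d, carbon fluxes g C/d, N and P fluxes
#'   g/d, tissue contents g).
#' @export
mussel_fluxes <- function(state, T, food, params) {
  stopifnot(inherits(params, "species_params"),
            params$species == "mussel")
  ws <- unname(state[["ws"]]); wg <- unname(state[["wg"]])
  if (ws < 0 || wg < 0) stop("mussel dry weights must be >= 0")
  food <- as.list(food)
  fv <- unlist(food[c("phyto_c", "det_zoo_c", "pom", "tsm", "cp", "np")])
  if (any(!is.finite(fv)) || any(fv < 0)) stop("negative food input")
  wd <- ws + wg

  tf_f <- temperature_response(T, params, "filtration")
  tf_c <- temperature_response(T, params, "catabolism")

  alw <- wd^pv(params, "b_cr")
  cr <- pv(params, "crmax") * tf_f * alw            # l/d
  f_p <- cr * food$phyto_c                          # mgC/d
  f_d <- cr * food$det_zoo_c
  filt <- f_p + f_d
  icap <- pv(params, "ing_cap") * alw               # mgC/d
  if (filt > icap) {
    ing <- icap
    pf <- filt - icap
  } else {
    ing <- filt
    pf <- 0
  }
  share_p <- if (filt > 0) f_p / filt else 0
  ing_p <- ing * share_p
  ing_d <- ing - ing_p
  absorbed <- pv(params, "ae_phyto") * ing_p + pv(params, "ae_det") * ing_d
  faeces_c_mg <- ing - absorbed

  A <- absorbed * pv(params, "en_food")             # J/d
  C <- pv(params, "k_cat") * tf_c * ws^pv(params, "n_cat")
  prod <- (A - C) / pv(params, "eps")               # g dry/d

  mature <- shell_length(c(ws = ws, wg = wg), params) >= pv(params, "l_mat")
  gfrac <- if (prod > 0 && mature && T >= pv(params, "t_gam"))
    pv(params, "gonad_frac") else 0
  d_soma <- (1 - gfrac) * prod
  d_gonad <- gfrac * prod

  # C (g/d) -> N, P (g/d) through the POC molar ratios
  cnp <- function(c_mg) {
    c_g <- c_mg / 1000
    p_mol <- if (food$cp > 0) (c_g / 12.011) / food$cp else 0
    c(c = c_g, n = p_mol * food$np * 14.007, p = p_mol * 30.974)
  }
  fa <- cnp(faeces_c_mg)
  pfa <- cnp(pf)

  flux <- c(anabolism = A, catabolism = C,
            filtered_c = filt / 1000, ingested_c = ing / 1000,
            pseudofaeces_c = unname(pfa["c"]),
            pseudofaeces_n = unname(pfa["n"]),
            pseudofaeces_p = unname(pfa["p"]),
            faeces_c = unname(fa["c"]),
            faeces_n = unname(fa["n"]),
            faeces_p = unname(fa["p"]),
            o2_consumption = 0, nh4_excretion = 0,
            tfun_filtration = tf_f, tfun_catabolism = tf_c,
            tissue_c = wd * pv(params, "tissue_c"),
            tissue_n = wd * pv(params, "tissue_n"),
            tissue_p = wd * pv(params, "tissue_p"))
  by <- metabolic_byproducts(flux, params)
  flux["o2_consumption"] <- by$O2
  flux["nh4_excretion"] <- by$NH4
  list(d_soma_dt = d_soma, d_gonad_dt = d_gonad, flux = flux)
}

#' Daily flux balance of a Manila clam individual
#'
#' The anabolic rate is proportional to a hyperbolic food response on
#' chlorophyll-a, the Gaussian temperature response, and the body surface
#' (`w^(2/3)`); the catabolic rate scales on weight with an exponential
#' temperature response: `A = a_ana * chl/(chl + k_chl) * Tfun_A * w^(2/3)`,
#' `C = k_cat * Tfun_C * w^n_cat`, `dw/dt = (A - C)/eps`.
#'
#' @param state Named numeric with element `w`, wet weight (g), > 0.
#' @param T Water temperature (degC).
#' @param chl Chlorophyll-a concentration (ug/l), >= 0.
#' @param params `species_params` for `"clam"`.
#' @return List with `dw_dt` (g/d) and `flux` (named numeric).
#' @export
clam_fluxes <- function(state, T, chl, params) {
  stopifnot(inherits(params, "species_params"), params$species == "clam")
  w <- unname(state[["w"]])
  if (!is.finite(w) || w <= 0) stop("non-positive clam weight")
  if (chl < 0) stop("chlorophyll must be >= 0")
  tf_a <- temperature_response(T, params, "anabolism")
  tf_c <- temperature_response(T, params, "catabolism")
  A <- pv(params, "a_ana") * (chl / (chl + pv(params, "k_chl"))) *
    tf_a * w^(2 / 3)
  C <- pv(params, "k_cat") * tf_c * w^pv(params, "n_cat")
  list(dw_dt = (A - C) / pv(params, "eps"),
       flux = c(anabolism = A, catabolism = C,
                tfun_anabolism = tf_a, tfun_catabolism = tf_c))
}

#' Shell length from body weight (shellfish only)
#'
#' Inverts the allometric length-weight relation `weight = aw * L^bw`:
#' mussel length (cm) from total dry weight, clam length (mm) from wet
#' weight. Monotone non-decreasing in weight; zero weight maps to zero
#' length. Finfish have no length output.
#'
#' @param state Named numeric state (`c(ws=, wg=)` for mussel, `c(w=)` for
#'   clam).
#' @param params `species_params` of a shellfish species.
#' @return Length in cm (mussel) or mm (clam).
#' @export
shell_length <- function(state, params) {
  stopifnot(inherits(params, "species_params"))
  species <- params$species
  if (is_finfish(species)) {
    stop("unsupported operation: no shell length for finfish species '",
         species, "'")
  }
  w <- if (species == "mussel") {
    unname(state[["ws"]] + state[["wg"]])
  } else unname(state[["w"]])
  if (w < 0) stop("weight must be >= 0")
  (w / pv(params, "aw"))^(1 / pv(params, "bw"))
}

# inverse of shell_length, used for thresholds expressed as lengths
weight_at_length <- function(length, params) {
  pv(params, "aw") * length^pv(params, "bw")
}

#' Oxygen consumption and ammonia excretion from the catabolic rate
#'
#' Respired energy is converted to oxygen mass through the oxycalorific
#' coefficient (`O2 = C / oxycal`); ammonia-nitrogen excretion is the
#' nitrogen content of the protein catabolized
#' (`NH4 = n_protein * prot_cat_frac * C / en_protein`). The species whose
#' parameter set lacks these coefficients (Manila clam) has no O2/NH4
#' output and calling this function for it raises a parameter error.
#'
#' @param flux Named numeric or list with element `catabolism` (J/d), >= 0.
#' @param params A `species_params` object.
#' @return List with `O2` (g O2/d) and `NH4` (g N/d).
#' @export
metabolic_byproducts <- function(flux, params) {
  stopifnot(inherits(params, "species_params"))
  C <- if (is.list(flux)) flux$catabolism else unname(flux[["catabolism"]])
  if (is.null(C) || !is.finite(C) || C < 0) {
    stop("flux record must carry a non-negative catabolism")
  }
  need <- c("oxycal", "prot_cat_frac", "n_protein", "en_protein")
  miss <- setdiff(need, names(params$params))
  if (length(miss)) {
    stop("parameter error: species '", params$species,
         "' lacks metabolic coefficients: ", paste(miss, collapse = ", "))
  }
  list(O2 = C / pv(params, "oxycal"),
       NH4 = pv(params, "n_protein") * pv(params, "prot_cat_frac") *
         C / pv(params, "en_protein"))
}

# units of each flux column, used in CSV headers
flux_units_map <- function(species) {
  switch(match_species(species),
    seabream = , seabass = c(
      anabolism = "J/d", catabolism = "J/d", ingestion = "g/d",
      uneaten_protein = "g/d", uneaten_lipid = "g/d", uneaten_carb = "g/d",
      faeces_protein = "g/d", faeces_lipid = "g/d", faeces_carb = "g/d",
      o2_consumption = "g/d", nh4_excretion = "gN/d",
      tfun_anabolism = "-", tfun_catabolism = "-"),
    mussel = c(
      anabolism = "J/d", catabolism = "J/d", filtered_c = "gC/d",
      ingested_c = "gC/d", pseudofaeces_c = "gC/d",
      pseudofaeces_n = "gN/d", pseudofaeces_p = "gP/d",
      faeces_c = "gC/d", faeces_n = "gN/d", faeces_p = "gP/d",
      o2_consumption = "g/d", nh4_excretion = "gN/d",
      tfun_filtration = "-", tfun_catabolism = "-",
      tissue_c = "gC", tissue_n = "gN", tissue_p = "gP"),
    clam = c(anabolism = "J/d", catabolism = "J/d",
             tfun_anabolism = "-", tfun_catabolism = "-"))
}
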