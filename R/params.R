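#' Species handled by the simulator
#'
#' The four Mediterranean farmed species covered by the package:
#' Mediterranean mussel (*Mytilus galloprovincialis*), Manila clam
#' (*Ruditapes philippinarum*), European seabass (*Dicentrarchus labrax*)
#' and gilthead seabream (*Sparus aurata*).
#'
#' @format Character vector of length 4.
#' @export
AQ_SPECIES <- c("mussel", "clam", "seabass", "seabream")

match_species <- function(species) {
  match.arg(tolower(species), AQ_SPECIES)
}

is_finfish <- function(species) species %in% c("seabass", "seabream")

#' Load the bioenergetic parameter set of a species
#'
#' Parameter sets are shipped as plain-text tables (one per species, columns
#' `symbol,value,units,description`) under `inst/extdata` and can be
#' overridden either from a user file with the same layout or through the
#' `overrides` list. Every symbol used by the flux equations of the species
#' must resolve; the energy density `eps` must be positive.
#'
#' @param species One of `"mussel"`, `"clam"`, `"seabass"`, `"seabream"`.
#' @param file Optional path to a replacement parameter table.
#' @param overrides Named list/vector of parameter values overriding the
#'   file (e.g. `list(crmax = 55)`).
#' @return An object of class `species_params`: list with elements
#'   `species` and `params` (named list of `list(value, units, description)`).
#' @examples
#' sp <- species_params("seabream")
#' param_value(sp, "eps")
#' @export
species_params <- function(species, file = NULL, overrides = list()) {
  species <- match_species(species)
  if (is.null(file)) {
    file <- system.file("extdata", paste0("params_", species, ".csv"),
                        package = "aquafarm", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("symbol", "value", "units", "description")
  if (!all(need %in% names(tab))) {
    stop("parameter file ", file, " must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$symbol)) {
    stop("duplicate parameter symbols in ", file)
  }
  params <- lapply(seq_len(nrow(tab)), function(i) {
    list(value = as.numeric(tab$value[i]), units = tab$units[i],
         description = tab$description[i])
  })
  names(params) <- tab$symbol
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be named")
    }
    for (nm in names(overrides)) {
      if (is.null(params[[nm]])) {
        params[[nm]] <- list(value = as.numeric(overrides[[nm]]),
                             units = "", description = "user override")
      } else {
        params[[nm]]$value <- as.numeric(overrides[[nm]])
      }
    }
  }
  obj <- structure(list(species = species, params = params),
                   class = "species_params")
  check_params(obj)
  obj
}

#' Extract a parameter value
#'
#' @param params A `species_params` object.
#' @param symbol Parameter symbol (character).
#' @return Numeric scalar.
#' @export
param_value <- function(params, symbol) {
  stopifnot(inherits(params, "species_params"))
  p <- params$params[[symbol]]
  if (is.null(p)) {
    stop("parameter '", symbol, "' is not defined for species '",
         params$species, "'")
  }
  p$value
}

# shorthand used throughout the flux equations
pv <- function(params, symbol) param_value(params, symbol)

required_symbols <- function(species) {
  common <- c("eps", "pc_cat", "tref_cat", "k_cat", "n_cat", "mortality")
  switch(species,
    seabream = ,
    seabass = c(common, "imax", "m", "topt_ana", "tsig_ana", "alpha_ana",
                "dig_protein", "dig_lipid", "dig_carb",
                "en_protein", "en_lipid", "en_carb",
                "oxycal", "prot_cat_frac", "n_protein", "w_commercial"),
    mussel = c(common, "crmax", "b_cr", "topt_filt", "tsig_filt", "ing_cap",
               "ae_phyto", "ae_det", "en_food", "gonad_frac", "l_mat",
               "t_gam", "spawn_ratio", "t_spawn", "aw", "bw", "dry_wet",
               "soft_total", "tissue_c", "tissue_n", "tissue_p",
               "oxycal", "prot_cat_frac", "n_protein", "en_protein",
               "c_to_chl", "l_commercial", "l_target"),
    clam = c(common, "a_ana", "k_chl", "topt_ana", "tsig_ana",
             "aw", "bw", "l_commercial"))
}

check_params <- function(obj) {
  miss <- setdiff(required_symbols(obj$species), names(obj$params))
  if (length(miss)) {
    stop("species '", obj$species, "' parameter set is missing: ",
         paste(miss, collapse = ", "))
  }
  vals <- vapply(obj$params, `[[`, numeric(1), "value")
  if (any(!is.finite(vals))) {
    stop("non-finite parameter values: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (pv(obj, "eps") <= 0) stop("energy density eps must be > 0")
  invisible(obj)
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params:", x$species, "> ", length(x$params),
      " parameters\n", sep = "")
  tab <- data.frame(
    symbol = names(x$params),
    value = vapply(x$params, `[[`, numeric(1), "value"),
    units = vapply(x$params, `[[`, character(1), "units"),
    row.names = NULL)
  print(tab, right = FALSE)
  invisible(x)
}
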