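# Flux equations: temperature responses, starvation limits, budget
# closures, allometry, metabolic by-products, and golden-value checks
# against the independently hand-coded oracle.

test_that("temperature responses are normalized, admissible and guarded", {
  cases <- list(
    list(sp = "seabream", proc = "anabolism", ref = "topt_ana"),
    list(sp = "seabream", proc = "catabolism", ref = "tref_cat"),
    list(sp = "seabass", proc = "anabolism", ref = "topt_ana"),
    list(sp = "mussel", proc = "filtration", ref = "topt_filt"),
    list(sp = "mussel", proc = "catabolism", ref = "tref_cat"),
    list(sp = "clam", proc = "anabolism", ref = "topt_ana"))
  for (cs in cases) {
    p <- species_params(cs$sp)
    # equals 1 at the form's optimum/reference temperature
    expect_equal(temperature_response(param_value(p, cs$ref), p, cs$proc), 1)
    # finite and non-negative over the 0..35 degC scan
    v <- vapply(seq(0, 35, by = 0.5), temperature_response, numeric(1),
                params = p, process = cs$proc)
    expect_true(all(is.finite(v) & v >= 0))
  }
  p <- species_params("mussel")
  expect_error(temperature_response(20, p, "anabolism"),
               "no temperature response")
  expect_error(temperature_response(45, p, "filtration"), "admissible")
  expect_error(temperature_response(-5, p, "catabolism"), "admissible")
})

test_that("finfish starvation and balance-point limits hold", {
  p <- species_params("seabream")
  fc <- feed_composition(0.5, 0.22, 0.28)
  out <- finfish_fluxes(c(w = 100), 20, 0, fc, p)
  fl <- out$flux
  expect_equal(unname(fl["ingestion"]), 0)
  expect_equal(unname(fl[c("uneaten_protein", "uneaten_lipid",
                           "uneaten_carb")]), rep(0, 3))
  expect_equal(unname(fl[c("faeces_protein", "faeces_lipid",
                           "faeces_carb")]), rep(0, 3))
  expect_equal(unname(fl["anabolism"]), 0)
  expect_lt(out$dw_dt, 0)
  expect_equal(out$dw_dt, -fl[["catabolism"]] / param_value(p, "eps"))

  # construct A = C: the energy balance point gives dw/dt = 0
  ample <- finfish_fluxes(c(w = 100), 20, 100, fc, p)$flux
  dig_e <- ample[["anabolism"]] / param_value(p, "alpha_ana") /
    ample[["ingestion"]]                    # digested energy per g feed
  r_star <- ample[["catabolism"]] / (param_value(p, "alpha_ana") * dig_e)
  bal <- finfish_fluxes(c(w = 100), 20, r_star, fc, p)
  expect_equal(bal$dw_dt, 0, tolerance = 1e-12)

  expect_error(finfish_fluxes(c(w = 0), 20, 1, fc, p), "weight")
  expect_error(finfish_fluxes(c(w = 10), 20, -1, fc, p), "ration")
})

test_that("finfish daily mass budget closes per macronutrient class", {
  set.seed(31)
  for (sp in c("seabream", "seabass")) {
    p <- species_params(sp)
    dig <- c(param_value(p, "dig_protein"), param_value(p, "dig_lipid"),
             param_value(p, "dig_carb"))
    for (i in 1:25) {
      w <- runif(1, 1, 800)
      T <- runif(1, 5, 30)
      r <- runif(1, 0, 10)
      f3 <- runif(3); f3 <- f3 / sum(f3)
      fc <- feed_composition(f3[1], f3[2], f3[3])
      fl <- finfish_fluxes(c(w = w), T, r, fc, p)$flux
      # ration = ingested + uneaten
      expect_equal(fl[["ingestion"]] + sum(fl[c("uneaten_protein",
                                                "uneaten_lipid",
                                                "uneaten_carb")]), r,
                   tolerance = 1e-9)
      # ingested = assimilated + faeces, class by class
      ing_k <- fl[["ingestion"]] * f3
      fae_k <- unname(fl[c("faeces_protein", "faeces_lipid",
                           "faeces_carb")])
      expect_equal(fae_k + ing_k * dig, ing_k, tolerance = 1e-9)
      expect_true(all(fl[setdiff(names(fl), c("tfun_anabolism",
                                              "tfun_catabolism"))] >= 0))
    }
  }
})

test_that("mussel filtration budget closes and the threshold is exact", {
  p <- species_params("mussel")
  food_lo <- list(phyto_c = 0.002, det_zoo_c = 0.005, pom = 1.2, tsm = 6,
                  cp = 106, np = 16)

  # zero food: no filtration, no ingestion, no pseudofaeces; both
  # compartments can only shrink
  z <- mussel_fluxes(c(ws = 0.5, wg = 0.05), 18,
                     list(phyto_c = 0, det_zoo_c = 0, pom = 0, tsm = 0,
                          cp = 106, np = 16), p)
  expect_equal(unname(z$flux[c("filtered_c", "ingested_c",
                               "pseudofaeces_c", "faeces_c")]), rep(0, 4))
  expect_lte(z$d_soma_dt, 0)
  expect_lte(z$d_gonad_dt, 0)

  # below the ingestion-capacity threshold pseudofaeces are exactly zero
  lo <- mussel_fluxes(c(ws = 0.5, wg = 0), 18, food_lo, p)$flux
  expect_identical(unname(lo[["pseudofaeces_c"]]), 0)
  expect_equal(lo[["filtered_c"]], lo[["ingested_c"]])

  # mass closure over random admissible inputs
  set.seed(41)
  en_food <- param_value(p, "en_food")
  for (i in 1:25) {
    st <- c(ws = runif(1, 0.01, 2), wg = runif(1, 0, 0.3))
    food <- list(phyto_c = runif(1, 0, 0.4), det_zoo_c = runif(1, 0, 1),
                 pom = 1.2, tsm = 6, cp = 106, np = 16)
    fl <- mussel_fluxes(st, runif(1, 5, 28), food, p)$flux
    expect_equal(fl[["filtered_c"]],
                 fl[["ingested_c"]] + fl[["pseudofaeces_c"]],
                 tolerance = 1e-9)
    absorbed_g <- fl[["anabolism"]] / en_food / 1000
    expect_equal(fl[["ingested_c"]], absorbed_g + fl[["faeces_c"]],
                 tolerance = 1e-9)
    expect_true(all(fl[setdiff(names(fl), c("tfun_filtration",
                                            "tfun_catabolism"))] >= 0))
  }

  expect_error(
    mussel_fluxes(c(ws = 1, wg = 0), 18,
                  list(phyto_c = -1, det_zoo_c = 0, pom = 0, tsm = 0,
                       cp = 106, np = 16), p),
    "negative food")
})

test_that("clam fluxes vanish without food and scale allometrically", {
  p <- species_params("clam")
  out <- clam_fluxes(c(w = 1), 20, 0, p)
  expect_equal(unname(out$flux[["anabolism"]]), 0)
  expect_lt(out$dw_dt, 0)

  a1 <- clam_fluxes(c(w = 1), 20, 2, p)$flux[["anabolism"]]
  a2 <- clam_fluxes(c(w = 2), 20, 2, p)$flux[["anabolism"]]
  expect_equal(a2 / a1, 2^(2 / 3), tolerance = 1e-12)

  expect_error(clam_fluxes(c(w = 0), 20, 2, p), "weight")
  expect_error(clam_fluxes(c(w = 1), 20, -2, p), "chlorophyll")
})

test_that("the energy balance has sign(A - C) for every species", {
  set.seed(51)
  pb <- species_params("seabream")
  pm <- species_params("mussel")
  pc <- species_params("clam")
  fc <- feed_composition(0.5, 0.22, 0.28)
  for (i in 1:20) {
    T <- runif(1, 5, 30)
    f <- finfish_fluxes(c(w = runif(1, 10, 500)), T, runif(1, 0, 8), fc, pb)
    expect_equal(sign(f$dw_dt),
                 sign(f$flux[["anabolism"]] - f$flux[["catabolism"]]))
    m <- mussel_fluxes(c(ws = runif(1, 0.05, 1), wg = 0), T,
                       list(phyto_c = runif(1, 0, .3),
                            det_zoo_c = runif(1, 0, .8),
                            pom = 1, tsm = 5, cp = 106, np = 16), pm)
    expect_equal(sign(m$d_soma_dt + m$d_gonad_dt),
                 sign(m$flux[["anabolism"]] - m$flux[["catabolism"]]))
    cl <- clam_fluxes(c(w = runif(1, 0.01, 3)), T, runif(1, 0, 6), pc)
    expect_equal(sign(cl$dw_dt),
                 sign(cl$flux[["anabolism"]] - cl$flux[["catabolism"]]))
  }
})

test_that("shell length is allometric, monotone and shellfish-only", {
  pm <- species_params("mussel")
  pc <- species_params("clam")
  expect_equal(shell_length(c(ws = 0, wg = 0), pm), 0)
  expect_equal(shell_length(c(w = 0), pc), 0)

  # strictly increasing over a weight scan
  w <- seq(0.01, 3, length.out = 40)
  lm_ <- vapply(w, function(x) shell_length(c(ws = x, wg = 0), pm),
                numeric(1))
  expect_true(all(diff(lm_) > 0))

  # inverse check against the allometric pair weight = aw * L^bw
  aw <- param_value(pm, "aw"); bw <- param_value(pm, "bw")
  for (L in c(2.5, 5, 7)) {
    expect_equal(shell_length(c(ws = aw * L^bw, wg = 0), pm), L,
                 tolerance = 1e-12)
  }
  # seeding weight of a 2.5 cm mussel
  expect_equal(shell_length(c(ws = 0.0333944, wg = 0), pm), 2.5,
               tolerance = 1e-4)

  expect_error(shell_length(c(w = 100), species_params("seabream")),
               "unsupported")
})

test_that("metabolic by-products follow the oxycalorific conversion", {
  p <- species_params("seabream")
  z <- metabolic_byproducts(c(catabolism = 0), p)
  expect_equal(z$O2, 0)
  expect_equal(z$NH4, 0)

  # 13560 J/d at 13560 J/gO2 is exactly 1 g O2/d
  expect_equal(metabolic_byproducts(c(catabolism = 13560), p)$O2, 1)

  # strictly increasing in the catabolic rate
  o2 <- vapply(c(100, 500, 2000, 8000), function(C)
    metabolic_byproducts(c(catabolism = C), p)$O2, numeric(1))
  expect_true(all(diff(o2) > 0))

  # the clam parameter set carries no metabolic coefficients
  expect_error(metabolic_byproducts(c(catabolism = 100),
                                    species_params("clam")),
               "parameter error")
})

test_that("flux evaluations match the hand-coded transcription oracle", {
  fc <- feed_composition(0.5, 0.22, 0.28)

  # seabream at three pinned (state, T, food) points
  pb <- species_params("seabream")
  for (pt in list(c(100, 20, 5), c(80, 14, 0.5), c(350, 26, 10))) {
    o <- oracle_seabream(pt[1], pt[2], pt[3])
    fl <- finfish_fluxes(c(w = pt[1]), pt[2], pt[3], fc, pb)
    expect_equal(fl$flux[["anabolism"]], o$A, tolerance = 1e-12)
    expect_equal(fl$flux[["catabolism"]], o$C, tolerance = 1e-12)
    expect_equal(fl$flux[["ingestion"]], o$ingestion, tolerance = 1e-12)
    expect_equal(unname(fl$flux[c("faeces_protein", "faeces_lipid",
                                  "faeces_carb")]), o$faeces,
                 tolerance = 1e-12)
    expect_equal(fl$dw_dt, o$dw_dt, tolerance = 1e-12)
    expect_equal(fl$flux[["o2_consumption"]], o$O2, tolerance = 1e-12)
    expect_equal(fl$flux[["nh4_excretion"]], o$NH4, tolerance = 1e-12)
  }
  # one frozen literal point guards oracle and implementation together
  o <- oracle_seabream(100, 20, 5)
  expect_equal(o$ingestion, 0.09 * exp(-(6 / 9)^2) * 100^0.67)
  expect_equal(o$C, 65 * 100^0.8)

  # seabass
  ps <- species_params("seabass")
  for (pt in list(c(24, 18, 1), c(150, 24, 3), c(300, 10, 0.2))) {
    o <- oracle_seabass(pt[1], pt[2], pt[3])
    fl <- finfish_fluxes(c(w = pt[1]), pt[2], pt[3], fc, ps)
    expect_equal(fl$flux[["anabolism"]], o$A, tolerance = 1e-12)
    expect_equal(fl$flux[["catabolism"]], o$C, tolerance = 1e-12)
    expect_equal(fl$dw_dt, o$dw_dt, tolerance = 1e-12)
  }

  # mussel: one point below and two above the pseudofaeces threshold
  pm <- species_params("mussel")
  for (pt in list(list(ws = 0.0334, wg = 0, T = 15, ph = 0.005, de = 0.01),
                  list(ws = 0.5, wg = 0.05, T = 18, ph = 0.1, de = 0.4),
                  list(ws = 1.2, wg = 0.2, T = 24, ph = 0.3, de = 0.9))) {
    o <- oracle_mussel(pt$ws, pt$wg, pt$T, pt$ph, pt$de)
    fl <- mussel_fluxes(c(ws = pt$ws, wg = pt$wg), pt$T,
                        list(phyto_c = pt$ph, det_zoo_c = pt$de,
                             pom = 1.2, tsm = 6, cp = 106, np = 16), pm)
    expect_equal(fl$flux[["anabolism"]], o$A, tolerance = 1e-12)
    expect_equal(fl$flux[["catabolism"]], o$C, tolerance = 1e-12)
    expect_equal(fl$flux[["filtered_c"]], o$filt, tolerance = 1e-12)
    expect_equal(fl$flux[["pseudofaeces_c"]], o$pf_c, tolerance = 1e-12)
    expect_equal(fl$flux[["faeces_c"]], o$fae_c, tolerance = 1e-12)
    expect_equal(fl$flux[["faeces_n"]], unname(o$fae_np["n"]),
                 tolerance = 1e-12)
    expect_equal(fl$flux[["faeces_p"]], unname(o$fae_np["p"]),
                 tolerance = 1e-12)
    expect_equal(fl$d_soma_dt, o$d_soma, tolerance = 1e-12)
    expect_equal(fl$d_gonad_dt, o$d_gonad, tolerance = 1e-12)
  }

  # clam
  pc <- species_params("clam")
  for (pt in list(c(1, 20, 2), c(0.007, 12, 0.8), c(2.5, 28, 5))) {
    o <- oracle_clam(pt[1], pt[2], pt[3])
    fl <- clam_fluxes(c(w = pt[1]), pt[2], pt[3], pc)
    expect_equal(fl$flux[["anabolism"]], o$A, tolerance = 1e-12)
    expect_equal(fl$flux[["catabolism"]], o$C, tolerance = 1e-12)
    expect_equal(fl$dw_dt, o$dw_dt, tolerance = 1e-12)
  }
})
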