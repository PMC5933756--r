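# Independent straight-line evaluations of the species flux formulations,
# with every constant typed in literally from the shipped parameter tables.
# These deliberately share no code with the package: they are the
# transcription oracle the golden-value tests compare against.

oracle_seabream <- function(w, T, ration, fp = 0.5, fl = 0.22, fc = 0.28) {
  tfa <- exp(-((T - 26) / 9)^2)
  tfc <- exp(0.069 * (T - 20))
  ing <- min(0.09 * tfa * w^0.67, ration)
  un <- ration - ing
  fae_p <- ing * fp * (1 - 0.89)
  fae_l <- ing * fl * (1 - 0.94)
  fae_c <- ing * fc * (1 - 0.55)
  dig_energy <- ing * fp * 0.89 * 23600 + ing * fl * 0.94 * 39500 +
    ing * fc * 0.55 * 17200
  A <- 0.35 * dig_energy
  C <- 65 * tfc * w^0.8
  list(A = A, C = C, ingestion = ing, uneaten = un,
       faeces = c(fae_p, fae_l, fae_c),
       dw_dt = (A - C) / 6500,
       O2 = C / 13560, NH4 = 0.16 * 0.6 * C / 23600,
       tfa = tfa, tfc = tfc)
}

oracle_seabass <- function(w, T, ration, fp = 0.5, fl = 0.22, fc = 0.28) {
  tfa <- exp(-((T - 24) / 8)^2)
  tfc <- exp(0.069 * (T - 20))
  ing <- min(0.08 * tfa * w^0.67, ration)
  fae_p <- ing * fp * (1 - 0.90)
  fae_l <- ing * fl * (1 - 0.93)
  fae_c <- ing * fc * (1 - 0.50)
  dig_energy <- ing * fp * 0.90 * 23600 + ing * fl * 0.93 * 39500 +
    ing * fc * 0.50 * 17200
  A <- 0.35 * dig_energy
  C <- 55 * tfc * w^0.8
  list(A = A, C = C, ingestion = ing, uneaten = ration - ing,
       faeces = c(fae_p, fae_l, fae_c),
       dw_dt = (A - C) / 6800,
       O2 = C / 13560, NH4 = 0.16 * 0.6 * C / 23600,
       tfa = tfa, tfc = tfc)
}

oracle_mussel <- function(ws, wg, T, phyto_c, det_c, cp = 106, np = 16) {
  wd <- ws + wg
  tff <- exp(-((T - 17) / 9)^2)
  tfc <- exp(0.074 * (T - 18))
  cr <- 66 * tff * wd^0.66              # l/d
  fp <- cr * phyto_c                    # mgC/d
  fd <- cr * det_c
  filt <- fp + fd
  icap <- 32 * wd^0.66
  if (filt > icap) { ing <- icap; pf <- filt - icap } else {
    ing <- filt; pf <- 0
  }
  shp <- if (filt > 0) fp / filt else 0
  absorbed <- 0.45 * ing * shp + 0.2 * ing * (1 - shp)
  fae <- ing - absorbed
  A <- absorbed * 45
  C <- 150 * tfc * ws^0.75
  prod <- (A - C) / 21000
  L <- (wd / 0.002137)^(1 / 3)
  gfrac <- if (prod > 0 && L >= 2 && T >= 12) 0.2 else 0
  to_np <- function(c_mg) {
    p_mol <- (c_mg / 1000 / 12.011) / cp
    c(n = p_mol * np * 14.007, p = p_mol * 30.974)
  }
  list(A = A, C = C, filt = filt / 1000, ing = ing / 1000,
       pf_c = pf / 1000, pf_np = to_np(pf),
       fae_c = fae / 1000, fae_np = to_np(fae),
       d_soma = (1 - gfrac) * prod, d_gonad = gfrac * prod,
       O2 = C / 13560, NH4 = 0.16 * 0.6 * C / 23600,
       tff = tff, tfc = tfc)
}

oracle_clam <- function(w, T, chl) {
  tfa <- exp(-((T - 22) / 8)^2)
  tfc <- exp(0.07 * (T - 20))
  A <- 70 * (chl / (chl + 1.5)) * tfa * w^(2 / 3)
  C <- 4 * tfc * w^1.0
  list(A = A, C = C, dw_dt = (A - C) / 2000, tfa = tfa, tfc = tfc)
}

# brute-force piecewise-linear interpolation used as the independent
# oracle for interpolate_daily
oracle_linear <- function(xs, ys, xout) {
  vapply(xout, function(x) {
    i <- max(which(xs <= x))
    if (xs[i] == x) return(ys[i])
    f <- (x - xs[i]) / (xs[i + 1] - xs[i])
    ys[i] * (1 - f) + ys[i + 1] * f
  }, numeric(1))
}
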