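## Independent term-by-term transcription of the model equations, kept
## deliberately separate from the package implementation: each displayed
## relation is written out literally and summed, with no shared helpers.

oracle_rhs <- function(state, p, lit, scenario = "ilid_drop") {
  K <- if (lit) p$partition_k_light else 1
  KA <- if (lit) p$ka_ilid_light else p$ka_ilid_dark

  ## cluster compartment: [LAT] = K [LAT]0
  LAT <- K * p$lat_total
  ## Zap70 equilibrium: bound fraction of LAT, plus free diffusion
  f <- p$zap70_cyt * KA / (1 + p$zap70_cyt * KA)
  Zap <- LAT * f + p$zap70_cyt
  ## LAT sub-pools by bound fraction
  L_bound_tot <- f * LAT
  L_free_tot <- (1 - f) * LAT

  Zp <- state[1]; Zp_cyt <- state[2]
  Lp_free <- state[3]; Lp_bound <- state[4]
  Zn <- Zap - Zp
  Zn_cyt <- p$zap70_cyt - Zp_cyt
  Ln_free <- L_free_tot - Lp_free
  Ln_bound <- L_bound_tot - Lp_bound

  ## Src equilibrium: active from total pLAT, inactive free-diffusing
  Src_a <- (Lp_free + Lp_bound) * p$src_cyt * p$ka_sh2 /
    (1 + p$src_cyt * p$ka_sh2)
  Src_i <- p$src_cyt

  ## PP2 non-competitive scaling of both Src rates
  kcat_a <- p$kcat_src_active * p$ki_pp2 / (p$ki_pp2 + p$pp2)
  kcat_i <- p$kcat_src_inactive * p$ki_pp2 / (p$ki_pp2 + p$pp2)

  dZp <- kcat_a * Src_a * Zn / (p$km_src_active + Zn) +
    kcat_i * Src_i * Zn / (p$km_src_inactive + Zn) -
    p$kdeph_zap70 * Zp
  dZp_cyt <- kcat_i * Src_i * Zn_cyt / (p$km_src_inactive + Zn_cyt) -
    p$kdeph_zap70 * Zp_cyt

  if (scenario == "zap70_k362e") {
    kinase <- Zap                       # both phospho-forms act
    complex <- Ln_bound                 # all bound LAT carries a Zap70
  } else {
    kinase <- Zp
    complex <- if (Zap > 0) Ln_bound * Zp / Zap else 0
  }
  dLp_free <- p$kcat_pzap70 * kinase * Ln_free /
    (p$km_pzap70 + Ln_free) - p$kdeph_lat * Lp_free
  dLp_bound <- p$kcat_pzap70 * kinase * Ln_bound /
    (p$km_pzap70 + Ln_bound) +
    p$k_tethered * complex - p$kdeph_lat * Lp_bound

  c(dZp, dZp_cyt, dLp_free, dLp_bound)
}

## Classical fixed-step RK4 on the oracle RHS.
oracle_rk4 <- function(x0, p, lit, t_end, dt, scenario = "ilid_drop") {
  n <- ceiling(t_end / dt)
  x <- x0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - (i - 1) * dt)
    k1 <- oracle_rhs(x, p, lit, scenario)
    k2 <- oracle_rhs(x + h / 2 * k1, p, lit, scenario)
    k3 <- oracle_rhs(x + h / 2 * k2, p, lit, scenario)
    k4 <- oracle_rhs(x + h * k3, p, lit, scenario)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

## Random, physically valid parameter set (moderate, non-stiff rates).
random_parameters <- function() {
  ka_d <- runif(1, 0, 1)
  model_parameters(
    lat_total = runif(1, 0.1, 2),
    zap70_cyt = runif(1, 0.2, 3),
    src_cyt = runif(1, 0.05, 2),
    ka_ilid_dark = ka_d,
    ka_ilid_light = ka_d + runif(1, 0, 20),
    ka_sh2 = runif(1, 0, 5),
    kcat_src_active = runif(1, 0, 5),
    km_src_active = runif(1, 0.5, 50),
    kcat_src_inactive = runif(1, 0, 0.05),
    km_src_inactive = runif(1, 0.05, 5),
    kdeph_zap70 = runif(1, 0.01, 0.5),
    kcat_pzap70 = runif(1, 0, 10),
    km_pzap70 = runif(1, 1, 100),
    k_tethered = runif(1, 0, 2),
    kdeph_lat = runif(1, 0.01, 0.5),
    ki_pp2 = runif(1, 0.2, 5),
    pp2 = runif(1, 0, 2),
    partition_k_light = runif(1, 1, 30))
}

## Random state strictly inside the physical box of a phase.
random_state <- function(p, lit) {
  cfg <- scenario_config("ilid_drop", light_on = lit)
  eq <- equilibrium_pools(p, cfg)
  model_state(
    pzap70_mem = runif(1, 0, eq$zap70_mem),
    pzap70_cyt = runif(1, 0, p$zap70_cyt),
    plat_free = runif(1, 0, eq$lat_free_total),
    plat_bound = runif(1, 0, eq$lat_bound_total))
}
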