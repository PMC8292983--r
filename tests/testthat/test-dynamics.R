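p0 <- model_parameters()

test_that("protocol validation catches bad durations", {
  expect_s3_class(light_protocol(), "light_protocol")
  expect_error(light_protocol(pre_dark_duration = -1), ">= 0")
  expect_error(light_protocol(sample_interval = 0), "> 0")
  expect_error(light_protocol(light_duration = 10, sample_interval = 20),
               "exceed")
})

test_that("integration reproduces first-order decay without kinases", {
  p <- update_parameters(p0, kcat_src_active = 0, kcat_src_inactive = 0,
                         kcat_pzap70 = 0, k_tethered = 0,
                         kdeph_lat = 0.01)
  cfg <- scenario_config("ilid_drop", light_on = FALSE)
  tc <- integrate_model(p, cfg, model_state(plat_free = 0.4), 100, 10)
  expect_equal(tc$plat_free[nrow(tc)], 0.4 * exp(-1), tolerance = 1e-6)
  ## the whole trajectory is exponential, not only the endpoint
  expect_equal(tc$plat_free, 0.4 * exp(-0.01 * tc$time),
               tolerance = 1e-6)
})

test_that("the all-zero phospho state is a fixed point without drive", {
  p <- update_parameters(p0, kcat_src_active = 0, kcat_src_inactive = 0,
                         kcat_pzap70 = 0, k_tethered = 0)
  cfg <- scenario_config("ilid_drop", light_on = TRUE)
  tc <- integrate_model(p, cfg, model_state(), 100, 10)
  expect_true(all(abs(as.matrix(tc[, 2:5])) < 1e-12))
})

test_that("adaptive integration matches a fine fixed-step reference", {
  set.seed(11)
  for (i in 1:5) {
    p <- random_parameters()
    lit <- i %% 2 == 0
    cfg <- scenario_config("ilid_drop", light_on = lit)
    x0 <- random_state(p, lit)
    tc <- integrate_model(p, cfg, x0, 5, 1)
    ref <- oracle_rk4(as.numeric(x0), p, lit, 5, 1e-3)
    got <- as.numeric(tc[nrow(tc), 2:5])
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("steady states satisfy the residual criterion and idempotence", {
  for (s in c("ilid_drop", "zap70_kd", "src_dsh2dsh3")) {
    sc <- apply_scenario(s, p0)
    ss <- steady_state(sc$params, sc$config, light_on = TRUE)
    expect_lt(attr(ss, "rhs_norm"), 1e-9)
    ## polishing a converged state does not move it
    ss2 <- steady_state(sc$params, sc$config, initial = ss,
                        light_on = TRUE)
    expect_equal(as.numeric(ss2), as.numeric(ss), tolerance = 1e-6)
  }
})

test_that("kinase-dead relaxation is exactly exponential in pLAT", {
  sc <- apply_scenario("zap70_kd", p0)
  x0 <- model_state(plat_free = 0.1, plat_bound = 0.02)
  tc <- integrate_model(sc$params, sc$config, x0, 200, 5,
                        light_on = FALSE)
  expect_equal(tc$plat_free + tc$plat_bound,
               0.12 * exp(-sc$params$kdeph_lat * tc$time),
               tolerance = 1e-7)
  ## and the steady state is the kinase-dead fixed point: pLAT = 0
  ss <- steady_state(sc$params, sc$config, light_on = FALSE)
  expect_equal(unname(ss[3] + ss[4]), 0, tolerance = 1e-7)
  expect_gt(unname(ss[1]), 0)  # leaky Src keeps some pZap70
})

test_that("pool redistribution preserves phospho-fractions at the switch", {
  cfg_d <- scenario_config("ilid_drop", light_on = FALSE)
  cfg_l <- scenario_config("ilid_drop", light_on = TRUE)
  eq_d <- equilibrium_pools(p0, cfg_d)
  eq_l <- equilibrium_pools(p0, cfg_l)
  st <- model_state(0.2, 0.05, 0.1, 0.01)
  sw <- redistribute_state(st, eq_d, eq_l)
  expect_equal(unname(sw[1]) / eq_l$zap70_mem,
               unname(st[1]) / eq_d$zap70_mem)
  expect_equal(unname(sw[3] + sw[4]) / eq_l$lat,
               unname(st[3] + st[4]) / eq_d$lat)
  ## the new bound/free split follows the new bound fraction
  expect_equal(unname(sw[4] / (sw[3] + sw[4])), eq_l$bound_fraction)
})

test_that("a zero-duration light phase returns the dark steady state", {
  sc <- apply_scenario("ilid_drop", p0)
  ex <- light_switch_experiment(sc$params, sc$config,
                                light_protocol(light_duration = 0))
  expect_equal(nrow(ex$lit_timecourse), 1L)
  expect_equal(ex$lit_frac, ex$dark_frac)
})

test_that("trajectories stay inside the physical box", {
  set.seed(12)
  for (i in 1:40) {
    p <- random_parameters()
    lit <- i %% 2 == 0
    cfg <- scenario_config("ilid_drop", light_on = lit)
    eq <- equilibrium_pools(p, cfg)
    tc <- integrate_model(p, cfg, random_state(p, lit), 50, 5)
    m <- as.matrix(tc[, 2:5])
    expect_true(all(m > -1e-8))
    expect_true(all(m[, 1] <= eq$zap70_mem + 1e-8))
    expect_true(all(m[, 3] <= eq$lat_free_total + 1e-8))
    expect_true(all(m[, 4] <= eq$lat_bound_total + 1e-8))
    expect_true(all(tc$plat_frac >= -1e-8 & tc$plat_frac <= 1 + 1e-8))
  }
})

test_that("the hysteresis probe reports both basins separately", {
  sc <- apply_scenario("ilid_drop", p0)
  hp <- hysteresis_probe(sc$params, sc$config, light_on = TRUE)
  expect_lt(attr(hp$from_low, "rhs_norm"), 1e-9)
  expect_lt(attr(hp$from_high, "rhs_norm"), 1e-9)
  expect_identical(hp$bistable,
                   abs(hp$frac_high - hp$frac_low) >
                     1e-4 * max(hp$frac_high, 1e-12))
  ## the lit clustered state is switched on from either side
  expect_gt(hp$frac_low, 0.5)
})

test_that("timecourses serialize to tidy CSV with a JSON sidecar", {
  sc <- apply_scenario("ilid_drop", p0)
  tc <- integrate_model(sc$params, sc$config, model_state(), 30, 10,
                        light_on = TRUE)
  f <- tempfile(fileext = ".csv")
  write_timecourse(tc, f)
  long <- read.csv(f)
  expect_setequal(names(long),
                  c("time_s", "scenario", "light", "variable", "value"))
  expect_true(all(c("plat_frac", "pzap70_mem") %in% long$variable))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$rtol, 1e-8)
  expect_equal(meta$scenario, "ilid_drop")
  unlink(c(f, paste0(f, ".json")))
})
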