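test_that("cluster concentration scales LAT by the partition coefficient", {
  expect_equal(cluster_concentration(1, 0.5), 0.5)
  expect_equal(cluster_concentration(10, 0.5), 5)
  expect_equal(cluster_concentration(10, 0), 0)
  expect_error(cluster_concentration(0, 0.5), "positive")
  expect_error(cluster_concentration(-2, 0.5), "positive")
  expect_error(cluster_concentration(0.5, 0.5), ">= 1")
})

test_that("Zap70 partition matches the equilibrium binding formula", {
  ## no binding: only free diffusion reaches the membrane
  z <- zap70_partition(10, 1, 0)
  expect_equal(z$total_mem, 1)
  expect_equal(z$bound, 0)
  expect_equal(z$free, 1)
  ## exact rational value: 10*1*10/(1+10) = 100/11
  z <- zap70_partition(10, 1, 10)
  expect_equal(z$bound, 100 / 11, tolerance = 1e-12)
  expect_equal(z$total_mem, 100 / 11 + 1, tolerance = 1e-12)
  ## saturation: bound -> [LAT] as KA -> Inf
  z <- zap70_partition(10, 1, 1e12)
  expect_equal(z$bound, 10, tolerance = 1e-9)
  expect_error(zap70_partition(-1, 1, 1), ">= 0")
})

test_that("bound Zap70 is capped by LAT and monotone in KA and Zap70", {
  for (i in 1:50) {
    set.seed(i)
    lat <- runif(1, 0, 10); zap <- runif(1, 0, 5)
    kas <- sort(runif(3, 0, 50))
    b <- vapply(kas, function(ka) zap70_partition(lat, zap, ka)$bound, 0)
    expect_true(all(diff(b) >= -1e-12))
    expect_true(all(b <= lat + 1e-12))
    zaps <- sort(runif(3, 0, 5))
    b2 <- vapply(zaps, function(z) zap70_partition(lat, z, kas[2])$bound, 0)
    expect_true(all(diff(b2) >= -1e-12))
  }
})

test_that("Src partition activates in proportion to phosphorylated LAT", {
  expect_equal(src_partition(0, 1, 5), list(active = 0, inactive = 1))
  expect_equal(src_partition(2, 1, 1), list(active = 1, inactive = 1))
  expect_equal(src_partition(2, 0, 1), list(active = 0, inactive = 0))
})

test_that("PP2 scaling is the non-competitive form", {
  expect_equal(pp2_scale(3, 1, 0), 3)
  expect_equal(pp2_scale(3, 1, 1), 1.5)   # exactly half at [PP2] = K_I
  expect_equal(pp2_scale(3, 1, 1e12), 0, tolerance = 1e-9)
  ## strictly decreasing in dose
  doses <- seq(0, 10, by = 0.5)
  expect_true(all(diff(pp2_scale(3, 2, doses)) < 0))
  expect_error(pp2_scale(3, 0, 1), "> 0")
})

test_that("rhs reduces to pure dephosphorylation without kinase activity", {
  p <- update_parameters(model_parameters(), kcat_src_active = 0,
                         kcat_src_inactive = 0, kcat_pzap70 = 0,
                         k_tethered = 0)
  cfg <- scenario_config("ilid_drop", light_on = FALSE)
  st <- model_state(plat_free = 0.2)
  d <- model_rhs(st, p, cfg)
  expect_equal(unname(d["plat_free"]), -p$kdeph_lat * 0.2)
  expect_equal(unname(d[c("pzap70_mem", "pzap70_cyt", "plat_bound")]),
               c(0, 0, 0))
})

test_that("kinase-dead scenario has no LAT phosphorylation gain", {
  sc <- apply_scenario("zap70_kd", model_parameters())
  for (lit in c(FALSE, TRUE)) {
    set.seed(42 + lit)
    st <- random_state(sc$params, lit)
    d <- model_rhs(st, sc$params, sc$config, light_on = lit)
    expect_equal(unname(d["plat_free"]),
                 -sc$params$kdeph_lat * unname(st["plat_free"]))
    expect_equal(unname(d["plat_bound"]),
                 -sc$params$kdeph_lat * unname(st["plat_bound"]))
  }
})

test_that("rhs agrees with an independent transcription on random draws", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_parameters()
    lit <- i %% 2 == 0
    st <- random_state(p, lit)
    cfg <- scenario_config("ilid_drop", light_on = lit)
    d <- model_rhs(st, p, cfg)
    o <- oracle_rhs(as.numeric(st), p, lit)
    expect_equal(unname(d), o, tolerance = 1e-12)
  }
})

test_that("rhs agrees with the oracle in the K362E regime", {
  set.seed(8)
  for (i in 1:20) {
    p0 <- random_parameters()
    sc <- apply_scenario("zap70_k362e", p0)
    lit <- i %% 2 == 0
    st <- random_state(sc$params, lit)
    d <- model_rhs(st, sc$params, sc$config, light_on = lit)
    o <- oracle_rhs(as.numeric(st), sc$params, lit,
                    scenario = "zap70_k362e")
    expect_equal(unname(d), o, tolerance = 1e-12)
  }
})

test_that("the physical box is forward-invariant at its faces", {
  set.seed(9)
  for (i in 1:25) {
    p <- random_parameters()
    lit <- i %% 2 == 0
    cfg <- scenario_config("ilid_drop", light_on = lit)
    eq <- equilibrium_pools(p, cfg)
    ## fully phosphorylated: every derivative must be <= 0
    hi <- model_state(eq$zap70_mem, p$zap70_cyt, eq$lat_free_total,
                      eq$lat_bound_total)
    expect_true(all(model_rhs(hi, p, cfg) <= 1e-12))
    ## all-zero phospho: every derivative must be >= 0
    expect_true(all(model_rhs(model_state(), p, cfg) >= -1e-12))
  }
})

test_that("states outside the pool bounds are rejected", {
  p <- model_parameters()
  cfg <- scenario_config("ilid_drop", light_on = FALSE)
  eq <- equilibrium_pools(p, cfg)
  bad <- c(eq$zap70_mem * 2, 0, 0, 0)
  expect_error(model_rhs(bad, p, cfg), "bounds")
  expect_error(model_state(pzap70_mem = -1), ">= 0")
})
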