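test_that("generators are pure functions of their seed", {
  a <- gen_gcamp_traces(25, seed = 10)
  b <- gen_gcamp_traces(25, seed = 10)
  expect_identical(a, b)
  c <- gen_gcamp_traces(25, seed = 11)
  expect_false(identical(a$traces$value, c$traces$value))
  ## the caller's RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_ktr_traces(5, seed = 1)); after <- runif(3)
  expect_identical(before, after)
  expect_error(gen_gcamp_traces(5, seed = NULL), "seed")
})

test_that("gcamp class proportions and grid match the spec", {
  g <- gen_gcamp_traces(100, responder_fraction = 0.3,
                        blinker_fraction = 0.2, seed = 12)
  expect_equal(as.vector(table(g$labels$class)[c("responder",
                                                 "blinker")]),
               c(30, 20))
  expect_equal(g$time, seq(0, 180, by = 5))
  expect_error(gen_gcamp_traces(10, responder_fraction = 0.7,
                                blinker_fraction = 0.5, seed = 1),
               "<= 1")
})

test_that("noiseless responders are perfectly separable", {
  g <- gen_gcamp_traces(30, responder_fraction = 1,
                        blinker_fraction = 0, noise_sd = 0, seed = 13)
  q <- quantify_traces(g$traces, protocol = "jurkat")
  expect_true(all(q$per_cell$responder))
  expect_equal(q$per_field$fraction_responding, 1)
})

test_that("ktr traces carry exact analytic AUC labels", {
  g <- gen_ktr_traces(8, noise_sd = 0, seed = 14)
  expect_equal(length(g$time), 61)  # 15-min protocol at 15 s
  q <- quantify_traces(g$traces, protocol = "fibroblast")
  ord <- match(q$per_cell$cell_id, g$labels$cell_id)
  expect_equal(q$per_cell$auc, g$labels$true_auc[ord], tolerance = 1e-9)
  nonresp <- g$labels$true_auc[g$labels$class == "nonresponder"]
  expect_true(all(nonresp == 0))
})

test_that("noisy ktr AUC errors stay within the noise-model bound", {
  n <- 200
  g <- gen_ktr_traces(n, noise_sd = 0.05, seed = 15)
  q <- quantify_traces(g$traces, protocol = "fibroblast")
  ord <- match(q$per_cell$cell_id, g$labels$cell_id)
  err <- q$per_cell$auc - g$labels$true_auc[ord]
  ## per-point ratio noise is multiplicative with log-sd sqrt(2)*0.05
  ## (two channels); the baselined sum subtracts the t = 0 ratio from
  ## the 60 later points, so the error sd is bounded by
  ## 0.0707 * sqrt(sum(ratio_t^2) + 60^2) <= 0.0707 * sqrt(61*3.5^2 +
  ## 3600) ~ 4.66, dominated by the shared-baseline term
  sd_bound <- sqrt(2) * 0.05 * sqrt(61 * 3.5^2 + 3600)
  expect_lt(mean(abs(err)), sd_bound)
  expect_lt(abs(mean(err)), 3 * sd_bound / sqrt(n))
  expect_lt(sd(err), 1.5 * sd_bound)
})

test_that("cluster images conserve masked intensity exactly", {
  img <- gen_cluster_images(n_clusters = 8, seed = 16)
  expect_equal(sum(img$post[img$mask]), sum(img$pre[img$mask]),
               tolerance = 1e-9)
  expect_true(all(img$pre[!img$mask] == 0))
  dcv <- membrane_cv_timeseries(list(img$pre, img$post), img$mask)
  expect_gt(dcv[2], 0.1)
})

test_that("CV change grows with punctum amplitude and vanishes without", {
  none <- gen_cluster_images(n_clusters = 0, noise_sd = 0.05, seed = 17)
  d0 <- membrane_cv_timeseries(list(none$pre, none$post), none$mask)[2]
  expect_lt(abs(d0), 0.02)
  amps <- c(1, 3, 6, 12)
  dcvs <- vapply(amps, function(a) {
    img <- gen_cluster_images(n_clusters = 6, cluster_amplitude = a,
                              noise_sd = 0.02, seed = 18)
    membrane_cv_timeseries(list(img$pre, img$post), img$mask)[2]
  }, 0)
  expect_true(all(diff(dcvs) > 0))
  ## every generated field shows a strictly positive clustering signal
  for (s in 19:28) {
    img <- gen_cluster_images(seed = s)
    expect_gt(membrane_cv_timeseries(list(img$pre, img$post),
                                     img$mask)[2], 0)
  }
})

test_that("noisy readouts reduce to the model curve at zero noise", {
  p <- model_parameters()
  doses <- c(0.1, 1, 10)
  obs <- gen_noisy_readouts(p, doses = doses, noise_sd = 0, seed = 20)
  expect_equal(obs$plat_frac, obs$plat_frac_true)
  expect_equal(obs$plat_frac_true,
               pp2_titration(doses, p)$plat_frac, tolerance = 1e-9)
  a <- gen_noisy_readouts(p, doses = doses, noise_sd = 0.05, seed = 21,
                          true_curve = pp2_titration(doses, p))
  b <- gen_noisy_readouts(p, doses = doses, noise_sd = 0.05, seed = 21,
                          true_curve = pp2_titration(doses, p))
  expect_identical(a, b)
  expect_true(all(a$plat_frac >= 0 & a$plat_frac <= 1))
})
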