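test_that("C/N ratio background-subtracts both channels", {
  expect_equal(cn_ratio(c(30, 40), c(20, 20), background = 10),
               c(2, 3))
  ## symmetric channels give a flat unit ratio
  expect_equal(cn_ratio(c(5, 7, 9), c(5, 7, 9), background = 2),
               rep(1, 3))
  ## a non-positive denominator is flagged, never clipped
  expect_warning(r <- cn_ratio(c(30, 40), c(20, 10), background = 10),
                 "flagged")
  expect_equal(r, c(2, NA))
  expect_error(cn_ratio(1:3, 1:2), "time grid")
})

test_that("AUC is the baselined plain sum, not a trapezoid", {
  expect_equal(trace_auc(c(2, 2, 2)), 0)
  expect_equal(trace_auc(c(1, 2, 3)), 3)
  ## 61-point unit step: 60 deviations of 1, whatever the time step
  step61 <- c(1, rep(2, 60))
  expect_equal(trace_auc(step61), 60)
  ## a trapezoid with dt = 15 s would give 892.5, not 60
  expect_false(isTRUE(all.equal(trace_auc(step61),
                                sum(diff(seq(0, 900, 15)) *
                                      (step61[-1] + step61[-61] - 2) / 2))))
  expect_error(trace_auc(1), "at least 2")
})

test_that("AUC is linear in the baselined trace", {
  set.seed(3)
  v <- runif(20, 1, 3)
  expect_equal(trace_auc(2.5 * v + 7), 2.5 * trace_auc(v))
})

test_that("min-normalization fixes the trace minimum at one", {
  expect_equal(normalize_gcamp(c(2, 4, 6)), c(1, 2, 3))
  expect_equal(min(normalize_gcamp(runif(10, 5, 9), background = 1)), 1)
  ## scale invariance of the raw signal
  v <- c(3, 8, 5)
  expect_equal(normalize_gcamp(17 * v), normalize_gcamp(v))
  expect_error(normalize_gcamp(c(1, 2), background = 1.5,
                               cell_id = "c7"), "c7")
})

test_that("sustained-response calls separate plateaus from blinks", {
  flat <- rep(1, 37)
  expect_false(sustained_response(flat))
  ## plateau: 10 samples >= half-max span 45 s
  plateau <- c(rep(1, 5), rep(3, 10), rep(1, 22))
  expect_true(sustained_response(plateau))
  ## a single 5-s spike is transient blinking
  spike <- rep(1, 37); spike[10] <- 3
  expect_false(sustained_response(spike))
  ## exactly 7 samples at dt = 5 span 30 s: the boundary qualifies
  run7 <- c(rep(1, 5), rep(3, 7), rep(1, 25))
  expect_true(sustained_response(run7))
  run6 <- c(rep(1, 5), rep(3, 6), rep(1, 26))
  expect_false(sustained_response(run6))
  ## two separated 15-s bursts never add up to 30 s
  split2 <- rep(1, 37); split2[5:8] <- 3; split2[20:23] <- 3
  expect_false(sustained_response(split2))
  expect_error(sustained_response(rep(1, 4)), "shorter")
})

test_that("sustained-response is scale-invariant and run-monotone", {
  base <- c(rep(1, 5), rep(3, 8), rep(1, 24))
  norm <- normalize_gcamp(base)
  expect_true(sustained_response(norm))
  expect_identical(sustained_response(normalize_gcamp(0.2 * base)),
                   sustained_response(norm))
  ## extending a qualifying plateau can never revoke the call
  for (len in 9:20) {
    v <- c(rep(1, 5), rep(3, len), rep(1, 37 - 5 - len))
    expect_true(sustained_response(v))
  }
})

test_that("the adaptive threshold option uses pre-stimulus noise", {
  quiet <- c(rep(1, 3), rep(1.2, 34))  # clean baseline, small response
  expect_true(sustained_response(quiet, noise_threshold = NULL))
  expect_false(sustained_response(quiet))  # below the fixed default
})

test_that("responder fractions are computed per field", {
  flat <- rep(1, 37)
  resp <- c(rep(1, 5), rep(3, 32))
  expect_equal(fraction_responding(list(resp, flat, flat, flat)), 0.25)
  expect_equal(fraction_responding(list(flat, flat)), 0)
  expect_equal(fraction_responding(list(resp, resp)), 1)
  expect_equal(fraction_responding(cbind(resp, flat)), 0.5)
  expect_error(fraction_responding(list()), "empty")
})

test_that("membrane CV change detects redistribution, not brightness", {
  mask <- matrix(TRUE, 4, 4)
  uni <- matrix(2, 4, 4)
  expect_equal(membrane_cv_timeseries(list(uni, uni, uni), mask),
               c(0, 0, 0))
  ## half pixels at 0, half at 2: CV = sd/mean = 1 (population CV of
  ## the two-point distribution; sample sd gives sqrt(16/15))
  bim <- matrix(c(0, 2), 4, 4)
  dcv <- membrane_cv_timeseries(list(uni, bim), mask)
  expect_equal(dcv[2], sqrt(16 / 15), tolerance = 1e-12)
  ## scale invariance
  expect_equal(membrane_cv_timeseries(list(uni * 3, bim * 3), mask), dcv)
  ## variance option is scale-dependent by design
  dvar <- membrane_cv_timeseries(list(uni, bim), mask,
                                 metric = "variance")
  expect_equal(dvar[2], var(rep(c(0, 2), 8)))
  expect_error(membrane_cv_timeseries(list(uni * 0), mask), "zero mean")
  expect_error(membrane_cv_timeseries(list(), mask), "empty")
})

test_that("tidy trace tables quantify end-to-end for both protocols", {
  g <- gen_ktr_traces(6, noise_sd = 0, seed = 4)
  q <- quantify_traces(g$traces, protocol = "fibroblast")
  expect_equal(nrow(q$per_cell), 6)
  ord <- match(q$per_cell$cell_id, g$labels$cell_id)
  expect_equal(q$per_cell$auc, g$labels$true_auc[ord], tolerance = 1e-9)

  j <- gen_gcamp_traces(20, responder_fraction = 0.5,
                        blinker_fraction = 0, noise_sd = 0.02,
                        field_size = 10, seed = 5)
  qj <- quantify_traces(j$traces, protocol = "jurkat")
  expect_equal(nrow(qj$per_field), 2)
  expect_equal(sum(qj$per_field$n_cells), 20)
  lab <- merge(qj$per_cell, j$labels, by = c("cell_id", "field_id"))
  expect_equal(lab$responder, lab$class == "responder")
})

test_that("image stacks and masks roundtrip through TIFF", {
  img <- gen_cluster_images(shape = c(32, 32), n_clusters = 3, seed = 6)
  f <- tempfile(fileext = ".tif")
  write_image_stack(list(img$pre, img$post), f)
  back <- read_image_stack(f)
  expect_length(back, 2)
  ## 16-bit quantization: shapes identical, values close after rescale
  sc <- max(img$pre, img$post)
  expect_equal(back[[2]] * sc, img$post, tolerance = 1e-3)
  fm <- tempfile(fileext = ".tif")
  write_mask(img$mask, fm)
  expect_identical(read_mask(fm), img$mask)
  unlink(c(f, fm))
})
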