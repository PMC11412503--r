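test_that("noiseless forward model is exact and severity 0 is lesion-free", {
  acq <- small_acq(48, 2)
  spec <- phantom_spec(seed = 11, severity = 0, snr = Inf)
  ph <- make_phantom(spec, acq)
  expect_equal(ph$truth$lesion_burden, 0)
  mus <- ph$truth$mask_true
  te <- acq$echo_times_ms
  for (k in c(1, 10, 30)) {
    vol <- ph$stack$data[, , , k]
    expect_equal(vol[mus],
                 rep(spec$s0_muscle * exp(-te[k] / spec$t2_healthy_ms), sum(mus)))
  }
})

test_that("lesion burden matches the commanded areal fractions", {
  acq <- small_acq(64, 2)
  spec <- phantom_spec(seed = 7, severity = 1, snr = Inf)
  ph <- make_phantom(spec, acq)
  target <- spec$lesion_fraction_mild(1) + spec$lesion_fraction_high(1)
  # voxel count on the generated field, against per-slice rounding error
  n_mus <- sum(ph$truth$mask_true)
  n_les <- sum(ph$truth$t2_field_ms[ph$truth$mask_true] > spec$t2_healthy_ms)
  expect_equal(ph$truth$lesion_burden, n_les / n_mus)
  expect_lt(abs(ph$truth$lesion_burden - target), acq$n_slices / n_mus + 1e-12)
  # and the two lesion classes individually
  n_high <- sum(ph$truth$t2_field_ms[ph$truth$mask_true] == spec$t2_lesion_high_ms)
  expect_lt(abs(n_high / n_mus - spec$lesion_fraction_high(1)),
            acq$n_slices / n_mus + 1e-12)
})

test_that("mean true muscle T2 is nondecreasing in severity", {
  acq <- small_acq(48, 2)
  means <- vapply(c(0, 0.3, 0.6, 1), function(s) {
    ph <- make_phantom(phantom_spec(seed = 21, severity = s, snr = Inf), acq)
    mean(ph$truth$t2_field_ms[ph$truth$mask_true])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("phantom generation is deterministic and noise seed only moves noise", {
  acq <- small_acq(32, 2)
  spec <- phantom_spec(seed = 5, severity = 0.4)
  a <- make_phantom(spec, acq)
  b <- make_phantom(spec, acq)
  expect_identical(a$stack$data, b$stack$data)
  c2 <- make_phantom(spec, acq, noise_seed = 999)
  expect_false(identical(a$stack$data, c2$stack$data))
  expect_identical(a$truth, c2$truth)
})

test_that("background magnitude follows the Rician (Rayleigh) noise floor", {
  acq <- small_acq(96, 2)
  spec <- phantom_spec(seed = 13, severity = 0, snr = 50)
  ph <- make_phantom(spec, acq)
  lab <- musclet2:::.build_anatomy(acq, TRUE)
  bg <- lab == 0
  expect_gte(sum(bg), 1e4)
  sigma <- musclet2:::.noise_sigma(spec, acq)
  expect_lt(abs(mean(ph$stack$data[, , , 1][bg]) / (sigma * sqrt(pi / 2)) - 1),
            0.05)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(severity = 1.2), "severity")
  expect_error(phantom_spec(t2_healthy_ms = 40, t2_lesion_mild_ms = 35), "t2_healthy")
  expect_error(phantom_spec(lesion_fraction_mild = function(s) -s), "fraction")
  expect_error(acq_params(echo_times_ms = numeric(0)), "echo_times")
  expect_error(acq_params(echo_times_ms = c(9, 9, 18)), "increasing")
})

test_that("retest pairs share ground truth with independent noise", {
  acq <- small_acq(32, 2)
  spec <- phantom_spec(seed = 3, severity = 0.5)
  expect_error(make_retest_pair(spec, acq, seed_a = 4, seed_b = 4), "differ")
  pr <- make_retest_pair(spec, acq, seed_a = 4, seed_b = 5)
  expect_false(identical(pr$stack_a$data, pr$stack_b$data))
  expect_true(any(pr$stack_a$data != pr$stack_b$data))
  # noise disabled: both members identical
  spec0 <- phantom_spec(seed = 3, severity = 0.5, snr = Inf)
  pr0 <- make_retest_pair(spec0, acq, seed_a = 4, seed_b = 5)
  expect_identical(pr0$stack_a$data, pr0$stack_b$data)
})

test_that("cohorts have the requested composition, dye model and determinism", {
  cs <- cohort_spec(n_per_group = c(WT = 5L, mdxB10 = 4L, mdxD2 = 3L))
  co <- make_cohort(cs, seed = 1, imaging = FALSE)
  expect_equal(nrow(co$records), 12)
  expect_equal(as.vector(table(co$records$genotype)[c("WT", "mdxB10", "mdxD2")]),
               c(5, 4, 3))
  expect_true(all(co$records$severity_true[co$records$genotype == "WT"] == 0))
  # severity 0 => burden 0 => dye = intercept exactly when noise-free
  cs0 <- cohort_spec(n_per_group = c(WT = 3L), dye_noise_sd = 0,
                     dye_intercept = 0.1, dye_slope = 2)
  co0 <- make_cohort(cs0, seed = 2, imaging = FALSE)
  expect_equal(co0$records$dye_uptake, rep(0.1, 3))
  # same seed -> bit-identical stacks
  acq <- small_acq(24, 1)
  cs_img <- cohort_spec(n_per_group = c(WT = 1L, mdxD2 = 1L))
  a <- make_cohort(cs_img, acq, seed = 9, imaging = TRUE)
  b <- make_cohort(cs_img, acq, seed = 9, imaging = TRUE)
  expect_identical(a$phantoms[[2]]$stack$data, b$phantoms[[2]]$stack$data)
  expect_identical(a$records, b$records)
})
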