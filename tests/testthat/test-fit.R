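te30 <- seq(9, by = 9, length.out = 30)

test_that("noiseless single-voxel fits are exact for both methods", {
  sig <- 1000 * exp(-te30 / 40)
  for (m in c("nls", "loglinear")) {
    f <- fit_voxel(sig, te30, method = m)
    expect_true(f$valid)
    expect_equal(f$t2_ms, 40, tolerance = 1e-6)
    expect_equal(f$s0, 1000, tolerance = 1e-6)
    expect_equal(f$fit_r2, 1, tolerance = 1e-6)
  }
})

test_that("degenerate signals are flagged invalid, not raised", {
  f <- fit_voxel(rep(0, 30), te30)
  expect_false(f$valid)
  # loglinear needs >= 3 strictly positive samples
  s <- c(5, 3, 0, 0, 0)
  f2 <- fit_voxel(s, te30[1:5], method = "loglinear")
  expect_false(f2$valid)
  expect_error(fit_voxel(c(1, 2), c(9, 18)), ">= 3")
})

test_that("fits are scale invariant in T2 and linear in S0", {
  set.seed(31)
  sig <- rician_decays(1, 35, te30, snr = 40)[1, ]
  for (m in c("nls", "loglinear")) {
    f1 <- fit_voxel(sig, te30, method = m)
    f2 <- fit_voxel(7.5 * sig, te30, method = m)
    expect_equal(f2$t2_ms, f1$t2_ms, tolerance = 1e-6)
    expect_equal(f2$s0, 7.5 * f1$s0, tolerance = 1e-6)
  }
})

test_that("noiseless fits are stable under echo subsampling", {
  sig <- 800 * exp(-te30 / 28)
  subsets <- list(1:30, seq(1, 30, by = 2), c(1, 2, 3), c(5, 15, 25, 30))
  t2s <- vapply(subsets, function(idx) {
    fit_voxel(sig[idx], te30[idx])$t2_ms
  }, numeric(1))
  expect_equal(t2s, rep(28, length(subsets)), tolerance = 1e-6)
})

test_that("vectorized nonlinear fit matches stats::nls on noisy voxels", {
  set.seed(17)
  S <- rician_decays(25, 25, te30, snr = 20)
  f <- musclet2:::.fit_nls_mat(S, te30)
  ref <- vapply(seq_len(nrow(S)), function(i) {
    fit <- stats::nls(y ~ a * exp(-te / b),
                      data = list(y = S[i, ], te = te30),
                      start = list(a = max(S[i, ]), b = 30),
                      algorithm = "port", lower = c(1e-12, 1),
                      upper = c(Inf, 1000),
                      control = stats::nls.control(maxiter = 500,
                                                   warnOnly = TRUE))
    stats::coef(fit)[["b"]]
  }, numeric(1))
  # both solvers stop at finite tolerances; agreement to 5e-3 ms
  expect_lt(max(abs(f$t2 - ref)), 5e-3)
})

test_that("under Rician noise the nonlinear fit beats log-linear (RMSE)", {
  set.seed(41)
  S <- rician_decays(2000, 25, te30, snr = 20)
  fn <- musclet2:::.fit_nls_mat(S, te30)
  fl <- musclet2:::.fit_loglinear_mat(S, te30)
  rmse <- function(x) sqrt(mean((x - 25)^2))
  expect_lt(rmse(fn$t2), rmse(fl$t2[fl$valid]))
})

test_that("fit_map recovers a noiseless two-region phantom exactly", {
  acq <- small_acq(48, 2)
  ph <- make_phantom(phantom_spec(seed = 8, severity = 0.6, snr = Inf), acq)
  mk <- muscle_mask(ph$truth$mask_true)
  map <- fit_map(ph$stack, mk)
  expect_equal(map$n_valid, sum(ph$truth$mask_true))
  expect_lt(max(abs(map$t2_ms[map$valid] - ph$truth$t2_field_ms[map$valid])),
            1e-6)
  # voxel counts per T2 value match ground truth
  for (v in c(25, 35, 65)) {
    expect_equal(sum(abs(map$t2_ms[map$valid] - v) < 1e-6),
                 sum(ph$truth$t2_field_ms[ph$truth$mask_true] == v))
  }
  # masking out a slice invalidates exactly that slice
  map2 <- fit_map(ph$stack, exclude_slices(mk, 2))
  expect_true(all(!map2$valid[, , 2]))
  expect_identical(map2$valid[, , 1], map$valid[, , 1])
  # all-invalid map raises a summary error
  zst <- echo_stack(array(0, c(8, 8, 1, 30)), acq$echo_times_ms)
  expect_error(fit_map(zst), "every voxel")
})

test_that("the optional constant-offset variant recovers an offset decay", {
  sig <- 600 * exp(-te30 / 30) + 20
  f <- fit_voxel(sig, te30, offset = TRUE)
  expect_true(f$valid)
  expect_equal(f$t2_ms, 30, tolerance = 1e-4)
  # the strict two-parameter model is biased on the same data
  f0 <- fit_voxel(sig, te30)
  expect_gt(f0$t2_ms, 31)
})
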