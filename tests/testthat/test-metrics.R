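test_that("tail trimming follows the linear-interpolation percentile convention", {
  # 1..1000: P1 = 10.99, P99 = 990.01 (type 7) -> closed interval keeps 11..990
  kept <- trim_tails(1:1000)
  expect_equal(sort(kept), 11:990)
  # identical values: trimming removes nothing
  expect_equal(trim_tails(rep(4.2, 100)), rep(4.2, 100))
  expect_error(trim_tails(numeric(0)), "empty")
  # stated retention bound: >= 0.98 n - 2, on random vectors
  set.seed(12)
  for (n in c(37, 120, 503)) {
    x <- rnorm(n)
    expect_gte(length(trim_tails(x)), 0.98 * n - 2)
  }
})

test_that("interdecile range matches hand and analytic oracles", {
  # 1..100 under type 7: P10 = 10.9, P90 = 90.1 -> IDR 79.2
  expect_equal(interdecile_range(1:100), 79.2)
  expect_equal(interdecile_range(rep(3, 10)), 0)
  expect_error(interdecile_range(5), "n >= 2")
  # large normal sample: IDR -> 2 * z_0.9 * sigma
  set.seed(22)
  x <- rnorm(1e6)
  expect_lt(abs(interdecile_range(x) - 2 * qnorm(0.9)), 0.01)
})

test_that("KDE mode finds the global density peak", {
  set.seed(33)
  x <- rnorm(1e5, 30, 2)
  expect_lt(abs(as.numeric(kde_mode(x)) - 30), 0.2)
  expect_warning(m <- kde_mode(rep(7, 50)), "degenerate")
  expect_equal(as.numeric(m), 7)
  expect_error(kde_mode(rnorm(5)), "n >= 10")
  # right-tailed mixture: global peak is the dominant low-T2 component
  xm <- c(rnorm(9e4, 25, 1), rnorm(1e4, 65, 3))
  expect_lt(abs(as.numeric(kde_mode(xm)) - 25), 0.5)
})

test_that("Pearson mode skew matches a component-wise recomputation", {
  set.seed(44)
  x <- c(rnorm(9e4, 25, 1), rnorm(1e4, 65, 3))
  sk <- pearson_mode_skew(x)
  expect_gt(sk, 0)
  # independent recomputation from separately computed parts
  d <- density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  ref <- (mean(x) - d$x[which.max(d$y)]) / sd(x)
  expect_equal(sk, ref, tolerance = 0.01)
  # symmetric samples: no systematic skew (KDE-mode noise at n = 1e5 is
  # ~0.06 sd units per draw, so assert the mean over seeds, not one draw)
  mean_skew <- mean(vapply(1:10, function(k) {
    withr::with_seed(900 + k, pearson_mode_skew(rnorm(1e5)))
  }, numeric(1)))
  expect_lt(abs(mean_skew), 0.05)
  # antisymmetry under negation (within KDE grid tolerance)
  expect_equal(pearson_mode_skew(-x), -sk, tolerance = 0.02)
  expect_warning(ps <- pearson_mode_skew(rep(1, 20)), "undefined")
  expect_true(is.na(ps))
})

test_that("D'Agostino K2 agrees with an external reference implementation", {
  # frozen from scipy.stats.normaltest on the identical draws
  set.seed(42)
  x1 <- rnorm(10000); x2 <- rexp(1000); x3 <- rnorm(50, 3, 2)
  r1 <- test_normality(x1)
  expect_equal(r1$statistic, 0.0882228268, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.9568473459, tolerance = 1e-8)
  r2 <- test_normality(x2)
  expect_equal(r2$statistic, 548.9528461335, tolerance = 1e-8)
  expect_lt(r2$p_value, 0.001)
  r3 <- test_normality(x3)
  expect_equal(r3$statistic, 0.2276947982, tolerance = 1e-8)
  expect_equal(r3$p_value, 0.8923941256, tolerance = 1e-8)
  expect_error(test_normality(rnorm(10)), "n >= 20")
})

test_that("extracted values match the map contents and ignore excluded slices", {
  acq <- small_acq(32, 3)
  ph <- make_phantom(phantom_spec(seed = 14, severity = 0.5, snr = Inf), acq)
  mk <- muscle_mask(ph$truth$mask_true)
  map <- fit_map(ph$stack, mk)
  v <- extract_values(map)
  # multiset matches ground truth voxel counts
  truth_vals <- ph$truth$t2_field_ms[ph$truth$mask_true]
  expect_equal(sort(v), sort(truth_vals), tolerance = 1e-9)
  # excluding one slice removes exactly that slice's values
  v2 <- extract_values(map, exclude_slices(mk, 2))
  expect_equal(length(v2), length(v) - sum(ph$truth$mask_true[, , 2]))
  expect_error(extract_values(map, exclude_slices(mk, 1:3)), "zero valid")
})

test_that("summaries are permutation invariant with honest degenerate handling", {
  acq <- small_acq(32, 2)
  ph0 <- make_phantom(phantom_spec(seed = 15, severity = 0, snr = Inf), acq)
  d0 <- suppressWarnings(phantom_metrics(ph0))
  expect_equal(d0$idr_ms, 0)
  expect_true(is.na(d0$pearson_skew))   # sd = 0: flagged, not invented
  expect_equal(d0$sd_ms, 0)
  # severe vs mild, same anatomy seed: both biomarkers strictly larger
  dm <- phantom_metrics(make_phantom(phantom_spec(seed = 16, severity = 0.2), acq))
  ds <- phantom_metrics(make_phantom(phantom_spec(seed = 16, severity = 0.9), acq))
  expect_gt(ds$idr_ms, dm$idr_ms)
  expect_gt(ds$pearson_skew, dm$pearson_skew)
})

test_that("metrics obey location-scale equivariance", {
  set.seed(55)
  x <- rexp(5000) * 10 + 20
  a <- 3.7; b <- 11
  y <- a * x + b
  expect_equal(interdecile_range(y), a * interdecile_range(x), tolerance = 1e-9)
  expect_equal(as.numeric(kde_mode(y)), a * as.numeric(kde_mode(x)) + b,
               tolerance = 0.05)
  expect_equal(pearson_mode_skew(y), pearson_mode_skew(x), tolerance = 0.01)
})

test_that("severe phantoms defeat the Gaussian summary (narrow peak, heavy tail)", {
  acq <- small_acq(48, 2)
  d <- phantom_metrics(make_phantom(phantom_spec(seed = 18, severity = 0.9), acq))
  v <- d$values_ms
  lo <- d$mode_ms - d$sd_ms; hi <- d$mode_ms + d$sd_ms
  emp_mass <- mean(v >= lo & v <= hi)
  gauss_mass <- pnorm(hi, d$mean_ms, d$sd_ms) - pnorm(lo, d$mean_ms, d$sd_ms)
  expect_lt(gauss_mass, 0.8 * emp_mass)
  # and the distribution is markedly non-normal
  expect_lt(d$normality_p, 0.001)
})
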