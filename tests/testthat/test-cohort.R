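test_that("Bland-Altman matches hand-computed oracles", {
  # identical pairs: bias 0, MDC 0 (with a zero-variance warning)
  expect_warning(ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$mdc, 0)
  # differences {+1, -1, +1, -1}: bias 0, sd = 2/sqrt(3), MDC = 1.96 * 2/sqrt(3)
  s1 <- c(10, 10, 10, 10)
  s2 <- c(11, 9, 11, 9)
  ba <- bland_altman(s1, s2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2 / sqrt(3))
  expect_equal(ba$mdc, 1.96 * 2 / sqrt(3))
  expect_equal(ba$loa_low, -1.96 * 2 / sqrt(3))
  expect_equal(ba$mdc_pct, 100 * ba$mdc / 10)
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("Bland-Altman limits contain ~95% of Gaussian differences", {
  set.seed(61)
  x <- rnorm(5000, 50, 5)
  y <- x + rnorm(5000, 0.5, 2)
  ba <- bland_altman(x, y)
  inside <- mean(y - x >= ba$loa_low & y - x <= ba$loa_high)
  expect_gte(inside, 0.90)
})

test_that("dye regression recovers exact lines and is rescale-equivariant", {
  rec <- data.frame(idr_ms = c(2, 4, 6, 8, 10),
                    pearson_skew = c(0.1, 0.2, 0.3, 0.4, 0.5))
  rec$dye_uptake <- 2 * rec$idr_ms + 1
  # lm warns about the machine-perfect fit; the point estimates are exact
  r <- suppressWarnings(regress_metric_vs_dye(rec, "idr"))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  # rescaling the metric rescales the slope, preserves sign and R^2
  set.seed(62)
  rec$dye_uptake <- 2 * rec$idr_ms + 1 + rnorm(5, 0, 0.3)
  r1 <- regress_metric_vs_dye(rec, "idr")
  rec2 <- rec; rec2$idr_ms <- rec$idr_ms * 1000
  r2 <- regress_metric_vs_dye(rec2, "idr")
  expect_equal(r2$slope, r1$slope / 1000, tolerance = 1e-9)
  expect_equal(sign(r2$slope), sign(r1$slope))
  expect_equal(r2$r_squared, r1$r_squared, tolerance = 1e-12)
  rec$idr_ms <- 5
  expect_error(regress_metric_vs_dye(rec, "idr"), "zero variance")
})

test_that("stratification ranks are permutation and affine invariant", {
  set.seed(63)
  rec <- data.frame(animal_id = sprintf("a%02d", 1:10),
                    genotype = rep(c("WT", "mdxB10"), each = 5),
                    idr_ms = runif(10, 2, 40),
                    pearson_skew = runif(10, 0, 0.8))
  s1 <- stratify_cohort(rec)
  perm <- rec[sample(10), ]
  s2 <- stratify_cohort(perm)
  expect_equal(s1$table$animal_id, s2$table$animal_id)
  aff <- rec
  aff$idr_ms <- 100 * aff$idr_ms - 3
  aff$pearson_skew <- 2 * aff$pearson_skew + 1
  s3 <- stratify_cohort(aff)
  expect_equal(s1$table$animal_id, s3$table$animal_id)
  expect_equal(s1$table$severity_rank, s3$table$severity_rank)
})

test_that("stratification rank tracks true severity within a genotype", {
  acq <- small_acq(40, 2)
  rhos <- vapply(1:3, function(k) {
    sev <- withr::with_seed(70 + k, runif(8, 0.05, 0.95))
    met <- t(vapply(seq_along(sev), function(i) {
      ph <- make_phantom(phantom_spec(seed = 700 + 10 * k + i,
                                      severity = sev[i]), acq)
      d <- phantom_metrics(ph)
      c(d$idr_ms, d$pearson_skew)
    }, numeric(2)))
    rec <- data.frame(animal_id = sprintf("m%d", seq_along(sev)),
                      idr_ms = met[, 1], pearson_skew = met[, 2],
                      severity_true = sev)
    tab <- stratify_cohort(rec)$table
    cor(tab$severity_rank, rank(tab$severity_true), method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.8)
})

test_that("serpentine balancing equalizes ranks and honors exclusions", {
  rec <- data.frame(idr_ms = c(1, 2, 3, 4, 5, 6),
                    pearson_skew = c(1, 2, 3, 4, 5, 6) / 10)
  g <- balance_groups(rec, 2)
  expect_equal(unname(table(g$group)), array(c(3L, 3L)))
  mr <- tapply(seq_len(6), g$group, mean)
  expect_lte(abs(mr[1] - mr[2]), 1)
  # exclusion bounds (10%, 90%) on 20 records -> 16 assigned
  rec20 <- data.frame(idr_ms = 1:20, pearson_skew = (1:20) / 10)
  g20 <- balance_groups(rec20, 4, exclude_quantiles = c(0.1, 0.9))
  expect_equal(sum(!is.na(g20$group)), 16)
  expect_true(all(is.na(g20$group[c(1, 2, 19, 20)])))
  expect_error(balance_groups(rec, 0), "n_groups")
})

test_that("severity-ranked balancing beats random assignment on average", {
  # constructed record tables: severity with monotone, noisy metrics
  set.seed(77)
  gap_bal <- numeric(500); gap_rnd <- numeric(500)
  for (k in 1:500) {
    sev <- runif(12)
    rec <- data.frame(idr_ms = 2 + 30 * sev + rnorm(12, 0, 1),
                      pearson_skew = 0.7 * sev + rnorm(12, 0, 0.05),
                      severity_true = sev)
    g <- balance_groups(rec, 2)
    gap_bal[k] <- abs(diff(tapply(g$severity_true, g$group, mean)))
    rnd <- sample(rep(1:2, 6))
    gap_rnd[k] <- abs(diff(tapply(sev, rnd, mean)))
  }
  expect_lt(mean(gap_bal), mean(gap_rnd))
})

test_that("convex-hull separability test is sound", {
  a <- cbind(c(0, 1, 0.5), c(0, 0, 1))
  b <- a + 5
  expect_true(musclet2:::.hulls_separable(a, b))
  expect_false(musclet2:::.hulls_separable(a, a + 0.1))
  # degenerate single points
  expect_true(musclet2:::.hulls_separable(matrix(c(0, 0), 1), matrix(c(3, 3), 1)))
})
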