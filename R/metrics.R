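# T2 histogram-shape biomarkers. All percentile computations use linear
# interpolation between order statistics (R's default type-7 quantile); the
# convention is recorded in every summary's provenance because IDR and the
# trim bounds depend on it.

.PCT_CONVENTION <- "linear interpolation (type 7)"

#' Extract muscle T2 values from a fitted map
#'
#' Values from valid voxels on non-excluded slices only; order-independent.
#'
#' @param map A `t2_map` from [fit_map()].
#' @param mask Optional [muscle_mask()] applied on top of the map's own
#'   validity (intersection), including its slice exclusions.
#' @return Numeric vector of T2 values in ms.
#' @export
extract_values <- function(map, mask = NULL) {
  stopifnot(inherits(map, "t2_map"))
  valid <- map$valid
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "muscle_mask"))
    if (!identical(dim(valid), dim(mask$labels))) {
      stop("shape mismatch: mask and map dimensions differ")
    }
    valid <- valid & mask$labels
    if (length(mask$excluded_slices)) valid[, , mask$excluded_slices] <- FALSE
  }
  v <- map$t2_ms[valid]
  if (length(v) == 0) stop("zero valid voxels after masking")
  v
}

#' Trim distribution tails by percentile
#'
#' Removes the bottom `lower_pct` and top `100 - upper_pct` percent of
#' values to reduce the influence of outliers on summary statistics. The
#' percentile bounds use linear interpolation between order statistics
#' (type 7) and the retained interval is closed (values equal to a bound
#' are kept).
#'
#' @param values Nonempty numeric vector.
#' @param lower_pct,upper_pct Percentile bounds (defaults 1 and 99).
#' @return The retained (unsorted) values.
#' @examples
#' length(trim_tails(1:1000))  # 980
#' @export
trim_tails <- function(values, lower_pct = 1, upper_pct = 99) {
  if (length(values) == 0) stop("empty input")
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  q <- stats::quantile(values, c(lower_pct, upper_pct) / 100, type = 7,
                       names = FALSE)
  values[values >= q[1] & values <= q[2]]
}

#' Interdecile range
#'
#' The difference between the 90th and 10th percentile values (type-7
#' percentiles); a robust measure of distribution spread that captures
#' heavy high-T2 tails.
#'
#' @param values Numeric vector, length >= 2.
#' @return Nonnegative scalar (same units as the input).
#' @export
interdecile_range <- function(values) {
  if (length(values) < 2) stop("interdecile_range requires n >= 2")
  q <- stats::quantile(values, c(0.1, 0.9), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Kernel-density mode
#'
#' Location of the peak of a Gaussian kernel density estimate with
#' Silverman's bandwidth, evaluated on a 512-point grid spanning
#' \[min, max\] and refined by local quadratic interpolation around the
#' grid argmax. Grid ties break toward the smaller value. A degenerate
#' sample (sd = 0) returns the common value with a warning. The bandwidth
#' used is attached as attribute `"bw"`.
#'
#' @param values Numeric vector (n >= 10 unless degenerate).
#' @param n_grid Grid size (default 512).
#' @return The mode location, with attribute `bw`.
#' @export
kde_mode <- function(values, n_grid = 512L) {
  if (length(values) == 0) stop("empty input")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("degenerate sample (sd = 0); mode is the common value")
    return(structure(values[1], bw = 0))
  }
  if (length(values) < 10) stop("kde_mode requires n >= 10")
  d <- stats::density(values, bw = "nrd0", n = n_grid,
                      from = min(values), to = max(values))
  i <- which.max(d$y)            # first maximum: ties toward smaller T2
  m <- d$x[i]
  if (i > 1 && i < n_grid) {
    denom <- d$y[i - 1] - 2 * d$y[i] + d$y[i + 1]
    if (denom < 0) {
      off <- (d$y[i - 1] - d$y[i + 1]) / (2 * denom)
      off <- max(-0.5, min(0.5, off))
      m <- d$x[i] + off * (d$x[2] - d$x[1])
    }
  }
  structure(m, bw = d$bw)
}

#' Pearson mode skewness
#'
#' `(mean - mode) / sd`, with the mode from [kde_mode()] and the sample
#' standard deviation (n - 1 denominator). Dimensionless; sensitive to a
#' disproportionate high-value tail. Undefined (NA, with a warning) when
#' sd = 0.
#'
#' @param values Numeric vector (n >= 10).
#' @return Scalar skewness, or `NA` when undefined.
#' @export
pearson_mode_skew <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("pearson_mode_skew undefined for sd = 0")
    return(NA_real_)
  }
  if (length(values) < 10) stop("pearson_mode_skew requires n >= 10")
  (mean(values) - as.numeric(kde_mode(values))) / s
}

#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the z-transformed sample skewness (D'Agostino
#' 1970) and kurtosis (Anscombe-Glynn 1983); under normality
#' `K2 = z_skew^2 + z_kurt^2` is chi-squared with 2 df. Requires n >= 20
#' (the kurtosis transform is undefined below that).
#'
#' @param values Numeric vector, n >= 20.
#' @return List with `statistic` and `p_value`.
#' @export
test_normality <- function(values) {
  n <- length(values)
  if (n < 20) stop("test_normality requires n >= 20")
  xc <- values - mean(values)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("test_normality undefined for a constant sample")
  b1 <- mean(xc^3) / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  b2 <- mean(xc^4) / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- zs^2 + zk^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Summarize a T2 map into its distribution biomarkers
#'
#' The full per-animal measurement: extract muscle T2 values, trim the
#' top and bottom tails, then compute mean, sd, interdecile range,
#' kernel-density mode, Pearson mode skewness and the D'Agostino K-squared
#' normality test on the trimmed sample. Degenerate samples (sd = 0) carry
#' `NA` skewness and normality results rather than errors. Provenance
#' (counts, percentile convention, KDE bandwidth, trim bounds) is recorded
#' in the returned object.
#'
#' @param map A `t2_map` from [fit_map()].
#' @param mask Optional [muscle_mask()] (see [extract_values()]).
#' @param trim Percentile trim bounds, default `c(1, 99)`.
#' @return Object of class `t2_distribution` with fields `values_ms`
#'   (sorted retained values), `n_raw`, `n_retained`, `mean_ms`, `sd_ms`,
#'   `mode_ms`, `idr_ms`, `pearson_skew`, `normality_stat`, `normality_p`,
#'   `kde_bw`, `trim_pct`, `percentile_convention`.
#' @export
summarize_t2 <- function(map, mask = NULL, trim = c(1, 99)) {
  raw <- extract_values(map, mask)
  v <- sort(trim_tails(raw, trim[1], trim[2]))
  s <- stats::sd(v)
  degenerate <- !is.finite(s) || s == 0
  mode_ms <- suppressWarnings(kde_mode(v))
  skew <- if (degenerate) NA_real_ else suppressWarnings(pearson_mode_skew(v))
  norm <- if (!degenerate && length(v) >= 20) test_normality(v) else
    list(statistic = NA_real_, p_value = NA_real_)
  structure(
    list(values_ms = v,
         n_raw = length(raw), n_retained = length(v),
         mean_ms = mean(v), sd_ms = s,
         mode_ms = as.numeric(mode_ms),
         idr_ms = if (length(v) >= 2) interdecile_range(v) else 0,
         pearson_skew = skew,
         normality_stat = norm$statistic, normality_p = norm$p_value,
         kde_bw = attr(mode_ms, "bw"),
         trim_pct = trim,
         percentile_convention = .PCT_CONVENTION),
    class = "t2_distribution"
  )
}

#' @export
print.t2_distribution <- function(x, ...) {
  cat(sprintf(paste0(
    "T2 distribution: n = %d (of %d raw)\n",
    "  mean %.2f ms, sd %.2f ms, mode %.2f ms (KDE bw %.3g)\n",
    "  IDR %.2f ms, Pearson mode skew %s\n",
    "  D'Agostino K2 = %s, p = %s\n"),
    x$n_retained, x$n_raw, x$mean_ms, x$sd_ms, x$mode_ms, x$kde_bw,
    x$idr_ms,
    if (is.na(x$pearson_skew)) "undefined (sd = 0)" else sprintf("%.3f", x$pearson_skew),
    if (is.na(x$normality_stat)) "NA" else sprintf("%.1f", x$normality_stat),
    if (is.na(x$normality_p)) "NA" else format(x$normality_p, digits = 3)))
  invisible(x)
}

#' One-row data frame of distribution metrics
#'
#' Convenience for building cohort tables from per-animal summaries.
#'
#' @param dist A `t2_distribution` from [summarize_t2()].
#' @param animal_id,genotype,session Optional identifiers.
#' @return A one-row data.frame.
#' @export
metrics_row <- function(dist, animal_id = NA_character_,
                        genotype = NA_character_, session = 1L) {
  stopifnot(inherits(dist, "t2_distribution"))
  data.frame(animal_id = animal_id, genotype = genotype, session = session,
             n_raw = dist$n_raw, n_retained = dist$n_retained,
             mean_ms = dist$mean_ms, sd_ms = dist$sd_ms,
             mode_ms = dist$mode_ms, idr_ms = dist$idr_ms,
             pearson_skew = dist$pearson_skew,
             normality_stat = dist$normality_stat,
             normality_p = dist$normality_p,
             kde_bw = dist$kde_bw,
             stringsAsFactors = FALSE)
}
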