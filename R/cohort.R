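# Cohort-level statistics: test-retest repeatability (Bland-Altman with
# minimum detectable change), metric-vs-dye regression, severity
# stratification and group balancing.

#' Bland-Altman analysis of paired test-retest measurements
#'
#' Bias is the mean of (session 2 - session 1) differences; the limits of
#' agreement are bias +/- 1.96 * sd of the differences (n - 1 denominator);
#' the minimum detectable change is `MDC = 1.96 * sd_diff` (equivalently
#' `1.96 * sqrt(2) * SEM` with `SEM = sd_diff / sqrt(2)`), reported also as
#' a percentage of the grand mean of all 2n measurements.
#'
#' @param s1,s2 Numeric vectors of first- and second-session measurements
#'   (same length, n >= 2).
#' @return Object of class `repeatability_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `mdc`, `mdc_pct`, `n`.
#' @examples
#' bland_altman(c(10, 11, 12), c(10.5, 10.8, 12.4))
#' @export
bland_altman <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  n <- length(s1)
  if (n < 2) stop("bland_altman requires n >= 2 pairs")
  d <- s2 - s1
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) warning("zero variance of differences; MDC is 0")
  mdc <- 1.96 * sd_diff
  grand <- mean(c(s1, s2))
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         mdc = mdc,
         mdc_pct = if (grand != 0) 100 * mdc / grand else NA_real_,
         n = n),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, LoA [%.4g, %.4g], MDC %.4g (%.3g%% of mean)\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$mdc, x$mdc_pct))
  invisible(x)
}

.metric_col <- function(metric) {
  switch(metric,
         idr = "idr_ms",
         skew = "pearson_skew",
         lesion_burden = "lesion_burden",
         stop("unknown metric: ", metric))
}

#' Simple linear regression of dye uptake on an imaging metric
#'
#' Ordinary least squares of `dye_uptake` on the chosen predictor (IDR,
#' Pearson skew, or the synthetic ground-truth lesion burden), the analogue
#' of validating the imaging biomarkers against the terminal Evans-blue-dye
#' assay.
#'
#' @param records Cohort data.frame with a `dye_uptake` column and the
#'   metric column (`idr_ms`, `pearson_skew` or `lesion_burden`).
#' @param metric One of `"idr"`, `"skew"`, `"lesion_burden"`.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `p_value`, `n`, `metric`.
#' @export
regress_metric_vs_dye <- function(records, metric = c("idr", "skew", "lesion_burden")) {
  metric <- match.arg(metric)
  col <- .metric_col(metric)
  if (!col %in% names(records) || !"dye_uptake" %in% names(records)) {
    stop("records must contain columns '", col, "' and 'dye_uptake'")
  }
  df <- records[stats::complete.cases(records[[col]], records$dye_uptake), ]
  if (nrow(df) < 3) stop("regression requires >= 3 records with dye values")
  x <- df[[col]]
  if (stats::sd(x) == 0) stop("zero variance in metric '", metric, "'")
  fit <- stats::lm(dye_uptake ~ x, data = data.frame(dye_uptake = df$dye_uptake, x = x))
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         slope_se = sm$coefficients[2, 2],
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = nrow(df), metric = metric),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("dye ~ %s (n = %d): slope %.4g (SE %.3g), intercept %.4g, R^2 = %.3f, p = %.3g\n",
              x$metric, x$n, x$slope, x$slope_se, x$intercept, x$r_squared,
              x$p_value))
  invisible(x)
}

#' Rank a cohort along the disease-severity spectrum
#'
#' Ranks animals by the rank-sum of their IDR rank and Pearson-skew rank (a
#' composite that is monotone in both metrics and invariant to affine
#' rescaling of either), and summarizes each genotype (median and IQR of
#' both metrics). The scatter table supports skew-vs-IDR stratification
#' plots.
#'
#' @param records Data.frame with `idr_ms` and `pearson_skew` columns (and
#'   optionally `animal_id`, `genotype`).
#' @return Object of class `stratification`: `table` (records ordered from
#'   mildest to most severe, with `rank_idr`, `rank_skew`, `severity_rank`),
#'   `group_summary`, `scatter`.
#' @export
stratify_cohort <- function(records) {
  if (nrow(records) < 2) stop("stratify requires >= 2 records")
  stopifnot(all(c("idr_ms", "pearson_skew") %in% names(records)))
  r1 <- rank(records$idr_ms, ties.method = "average")
  r2 <- rank(records$pearson_skew, ties.method = "average")
  ranksum <- r1 + r2
  sev_rank <- rank(ranksum, ties.method = "average")
  tab <- records
  tab$rank_idr <- r1
  tab$rank_skew <- r2
  tab$severity_rank <- sev_rank
  ord <- order(ranksum,
               if (!is.null(records$animal_id)) records$animal_id else seq_len(nrow(records)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  group_summary <- NULL
  if (!is.null(records$genotype)) {
    group_summary <- do.call(rbind, lapply(split(records, records$genotype), function(g) {
      data.frame(genotype = g$genotype[1], n = nrow(g),
                 idr_median = stats::median(g$idr_ms),
                 idr_iqr = stats::IQR(g$idr_ms),
                 skew_median = stats::median(g$pearson_skew),
                 skew_iqr = stats::IQR(g$pearson_skew),
                 stringsAsFactors = FALSE)
    }))
    rownames(group_summary) <- NULL
  }
  scatter_cols <- intersect(c("animal_id", "genotype", "idr_ms", "pearson_skew"),
                            names(records))
  structure(list(table = tab, group_summary = group_summary,
                 scatter = records[, scatter_cols, drop = FALSE]),
            class = "stratification")
}

#' Balance animals across treatment groups by severity rank
#'
#' Serpentine (snake) assignment over the severity ranking from
#' [stratify_cohort()]: the ordered animals are dealt 1..k, k..1, 1..k, ...
#' so group mean ranks stay close. Optionally excludes animals whose rank
#' percentile `(rank - 0.5) / n` falls outside `exclude_quantiles` --
#' the a-priori exclusion of extremely mild or extremely severe animals.
#'
#' @param records Data.frame with `idr_ms` and `pearson_skew` columns.
#' @param n_groups Number of treatment groups (>= 1).
#' @param exclude_quantiles Optional `c(lo, hi)` rank-percentile bounds,
#'   e.g. `c(0.1, 0.9)`.
#' @return `records` with added columns `severity_rank` and `group`
#'   (NA for excluded animals), ordered by severity rank.
#' @export
balance_groups <- function(records, n_groups, exclude_quantiles = NULL) {
  if (n_groups < 1) stop("invalid parameter: n_groups must be >= 1")
  if (nrow(records) < n_groups) stop("fewer records than groups")
  tab <- stratify_cohort(records)$table
  n <- nrow(tab)
  keep <- rep(TRUE, n)
  if (!is.null(exclude_quantiles)) {
    p <- (seq_len(n) - 0.5) / n
    keep <- p >= exclude_quantiles[1] & p <= exclude_quantiles[2]
  }
  kept_idx <- which(keep)
  k <- length(kept_idx)
  cycle <- c(seq_len(n_groups), rev(seq_len(n_groups)))
  assign <- rep(cycle, length.out = k)
  tab$group <- NA_integer_
  tab$group[kept_idx] <- assign
  tab
}

# --- 2-D linear separability (separating-axis test on convex hulls) ------

# TRUE when the convex hulls of two 2-D point sets are disjoint, i.e. the
# sets are strictly linearly separable. Used for Fig-4-style group
# separation checks.
.hulls_separable <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2)
  axes <- list()
  edge_normals <- function(pts) {
    if (nrow(pts) < 2) return(NULL)
    h <- pts[grDevices::chull(pts), , drop = FALSE]
    nh <- nrow(h)
    e <- h[c(seq_len(nh)[-1], 1), , drop = FALSE] - h
    cbind(-e[, 2], e[, 1])
  }
  axes <- rbind(edge_normals(a), edge_normals(b),
                matrix(colMeans(b) - colMeans(a), 1, 2))
  axes <- axes[rowSums(axes^2) > 0, , drop = FALSE]
  for (i in seq_len(nrow(axes))) {
    ax <- axes[i, ]
    pa <- a %*% ax
    pb <- b %*% ax
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}
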