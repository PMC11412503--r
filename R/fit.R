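# Voxelwise monoexponential T2 fitting: S(TE) = S0 * exp(-TE / T2).
#
# The nonlinear route is a vectorized Levenberg-Marquardt over all voxels at
# once (per-voxel 2x2 normal equations in closed form, per-voxel damping),
# initialized from the log-linear solution, with box bounds on T2. Voxels
# whose fitted T2 lands on a bound are flagged invalid rather than clipped
# so they cannot silently distort distribution tails.

.T2_BOUNDS <- c(1, 1000)
.FIT_TOL <- 1e-8
.FIT_MAXIT <- 200L

# Log-linear fit of ln S on TE per row, using only strictly positive
# samples. Returns NA-filled results for rows with < 3 usable samples.
.fit_loglinear_mat <- function(S, te) {
  pos <- S > 0
  n <- rowSums(pos)
  ls <- matrix(0, nrow(S), ncol(S))
  ls[pos] <- log(S[pos])
  sx <- rowSums(sweep(pos, 2, te, `*`))
  sy <- rowSums(ls)
  sxx <- rowSums(sweep(pos, 2, te^2, `*`))
  sxy <- rowSums(sweep(ls, 2, te, `*`))
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  inter <- (sy - slope * sx) / n
  t2 <- -1 / slope
  s0 <- exp(inter)
  usable <- n >= 3 & denom > 0
  # goodness of fit in signal space, over all echoes
  pred <- s0 * exp(outer(-1 / t2, te))
  pred[!usable, ] <- NA_real_
  r2 <- .signal_r2(S, pred)
  valid <- usable & is.finite(t2) & t2 > 0 & is.finite(s0) & s0 > 0
  list(t2 = t2, s0 = s0, r2 = r2, valid = valid)
}

.signal_r2 <- function(S, pred) {
  rss <- rowSums((S - pred)^2)
  tss <- rowSums((S - rowMeans(S))^2)
  r2 <- 1 - rss / tss
  r2[tss == 0] <- NA_real_
  r2
}

# Vectorized Levenberg-Marquardt for the 2-parameter exponential.
.fit_nls_mat <- function(S, te, t2_bounds = .T2_BOUNDS, tol = .FIT_TOL,
                         maxit = .FIT_MAXIT) {
  nv <- nrow(S)
  ini <- .fit_loglinear_mat(S, te)
  t2 <- ifelse(is.finite(ini$t2) & ini$t2 > 0, ini$t2,
               mean(te))           # fallback start in the middle of the TE range
  t2 <- pmin(pmax(t2, t2_bounds[1]), t2_bounds[2])
  s0 <- ifelse(is.finite(ini$s0) & ini$s0 > 0, ini$s0, pmax(S[, 1], 1e-6))
  s0 <- pmax(s0, 1e-12)
  degenerate <- rowSums(S > 0) < 3
  lam <- rep(1e-3, nv)
  conv <- degenerate                      # do not iterate degenerate rows
  E <- exp(outer(-1 / t2, te))
  rss <- rowSums((S - s0 * E)^2)
  it <- 0L
  while (it < maxit && !all(conv)) {
    it <- it + 1L
    R <- S - s0 * E
    D <- s0 * sweep(E, 2, te, `*`) / t2^2
    A11 <- rowSums(E^2); A12 <- rowSums(E * D); A22 <- rowSums(D^2)
    g1 <- rowSums(E * R); g2 <- rowSums(D * R)
    M11 <- A11 * (1 + lam); M22 <- A22 * (1 + lam)
    det <- M11 * M22 - A12^2
    d1 <- (M22 * g1 - A12 * g2) / det
    d2 <- (-A12 * g1 + M11 * g2) / det
    s0n <- pmax(s0 + d1, 1e-12)
    t2n <- pmin(pmax(t2 + d2, t2_bounds[1]), t2_bounds[2])
    En <- exp(outer(-1 / t2n, te))
    rssn <- rowSums((S - s0n * En)^2)
    acc <- !conv & is.finite(rssn) & rssn <= rss
    rel <- abs(rss - rssn) / pmax(rss, 1e-300)
    conv <- conv | (acc & rel < tol) | (!conv & !acc & lam >= 1e9)
    lam <- ifelse(conv, lam, ifelse(acc, pmax(lam / 3, 1e-12), pmin(lam * 5, 1e10)))
    s0 <- ifelse(acc, s0n, s0)
    t2 <- ifelse(acc, t2n, t2)
    E[acc, ] <- En[acc, , drop = FALSE]
    rss <- ifelse(acc, rssn, rss)
  }
  eps <- 1e-6
  at_bound <- t2 <= t2_bounds[1] + eps | t2 >= t2_bounds[2] - eps
  r2 <- .signal_r2(S, s0 * E)
  valid <- !degenerate & conv & !at_bound & is.finite(t2) & is.finite(s0) & s0 > 0
  list(t2 = t2, s0 = s0, r2 = r2, valid = valid, converged = conv)
}

# Constant-offset variant S0 * exp(-TE/T2) + C, fitted per voxel with
# stats::nls (port). Rarely used (off by default); slower by design.
.fit_offset_row <- function(y, te, t2_bounds) {
  st <- list(a = max(y), b = min(max(mean(te) / 3, t2_bounds[1]), t2_bounds[2]),
             cc = min(y))
  fit <- try(stats::nls(y ~ a * exp(-te / b) + cc,
                        data = list(y = y, te = te), start = st,
                        algorithm = "port",
                        lower = c(1e-12, t2_bounds[1], 0),
                        upper = c(Inf, t2_bounds[2], Inf),
                        control = stats::nls.control(maxiter = 500,
                                                     warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(c(NA_real_, NA_real_, NA_real_, 0))
  }
  cf <- stats::coef(fit)
  pred <- cf[["a"]] * exp(-te / cf[["b"]]) + cf[["cc"]]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - pred)^2) / tss else NA_real_
  c(cf[["b"]], cf[["a"]], r2, 1)
}

#' Fit the monoexponential decay model to one voxel
#'
#' Fits `S(TE) = S0 * exp(-TE / T2)` to a single echo train. The `nls`
#' method is nonlinear least squares (Levenberg-Marquardt) initialized from
#' the log-linear solution, with T2 bounded to \[1, 1000\] ms; `loglinear`
#' is ordinary least squares of `ln S` on TE over strictly positive samples.
#' Degenerate input (fewer than 3 usable samples, e.g. all-zero signal) or
#' non-convergence yields `valid = FALSE`, never an exception; a fitted T2
#' on a bound is likewise flagged invalid.
#'
#' @param signal Numeric vector of magnitudes, one per echo.
#' @param echo_times_ms Strictly increasing echo times, length >= 3.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @param offset Add a constant noise-floor offset term (nls only; off by
#'   default -- the model is then strictly the two-parameter decay).
#' @param drop_first_echo Discard the first echo before fitting.
#' @param t2_bounds T2 box bounds in ms for the nls route.
#' @return List with `t2_ms`, `s0`, `fit_r2`, `valid`.
#' @examples
#' te <- seq(9, by = 9, length.out = 30)
#' fit_voxel(1000 * exp(-te / 40), te)
#' @export
fit_voxel <- function(signal, echo_times_ms, method = c("nls", "loglinear"),
                      offset = FALSE, drop_first_echo = FALSE,
                      t2_bounds = c(1, 1000)) {
  method <- match.arg(method)
  signal <- as.numeric(signal)
  echo_times_ms <- as.numeric(echo_times_ms)
  stopifnot(length(signal) == length(echo_times_ms))
  if (length(echo_times_ms) < 3 || any(diff(echo_times_ms) <= 0)) {
    stop("invalid parameter: need >= 3 strictly increasing echo times")
  }
  if (!all(is.finite(signal))) stop("invalid parameter: signal must be finite")
  if (drop_first_echo) {
    signal <- signal[-1]; echo_times_ms <- echo_times_ms[-1]
  }
  S <- matrix(signal, nrow = 1)
  if (method == "loglinear") {
    f <- .fit_loglinear_mat(S, echo_times_ms)
  } else if (offset) {
    r <- .fit_offset_row(signal, echo_times_ms, t2_bounds)
    f <- list(t2 = r[1], s0 = r[2], r2 = r[3], valid = r[4] == 1)
  } else {
    f <- .fit_nls_mat(S, echo_times_ms, t2_bounds)
  }
  list(t2_ms = unname(f$t2[1]), s0 = unname(f$s0[1]),
       fit_r2 = unname(f$r2[1]), valid = unname(f$valid[1]))
}

#' Fit a T2 map over the masked region of an echo stack
#'
#' Applies [fit_voxel()]'s model to every valid voxel (vectorized).
#' Non-mask voxels and voxels on excluded slices are invalid; per-voxel
#' failures (degenerate signal, non-convergence, bound hits) are flagged,
#' not raised. Deterministic for fixed inputs.
#'
#' @param stack An [echo_stack()].
#' @param mask Optional [muscle_mask()]; `NULL` fits every voxel.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @param offset,drop_first_echo,t2_bounds See [fit_voxel()].
#' @return Object of class `t2_map`: arrays `t2_ms`, `s0`, `fit_r2` (NA
#'   where invalid), logical `valid`, plus `method`, `t2_bounds_ms`,
#'   `n_valid`, `n_failed`, `echo_times_ms`.
#' @export
fit_map <- function(stack, mask = NULL, method = c("nls", "loglinear"),
                    offset = FALSE, drop_first_echo = FALSE,
                    t2_bounds = c(1, 1000)) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "echo_stack"))
  d <- dim(stack$data)
  valid3 <- if (is.null(mask)) {
    array(TRUE, dim = d[1:3])
  } else {
    apply_mask(stack, mask)$valid
  }
  idx <- which(valid3)
  if (length(idx) == 0) stop("no valid voxels to fit (empty mask?)")
  te <- stack$echo_times_ms
  Smat <- matrix(stack$data, nrow = prod(d[1:3]), ncol = d[4])[idx, , drop = FALSE]
  if (drop_first_echo) {
    Smat <- Smat[, -1, drop = FALSE]; te <- te[-1]
  }
  if (length(te) < 3) stop("invalid parameter: need >= 3 echoes")
  f <- if (method == "loglinear") {
    .fit_loglinear_mat(Smat, te)
  } else if (offset) {
    r <- t(apply(Smat, 1, .fit_offset_row, te = te, t2_bounds = t2_bounds))
    list(t2 = r[, 1], s0 = r[, 2], r2 = r[, 3], valid = r[, 4] == 1)
  } else {
    .fit_nls_mat(Smat, te, t2_bounds)
  }
  mk <- function(vals, ok) {
    a <- array(NA_real_, dim = d[1:3])
    a[idx[ok]] <- vals[ok]
    a
  }
  ok <- f$valid
  valid_out <- array(FALSE, dim = d[1:3])
  valid_out[idx[ok]] <- TRUE
  if (!any(valid_out)) {
    stop("fit failed for every voxel in the mask (all-invalid T2 map)")
  }
  structure(
    list(t2_ms = mk(f$t2, ok), s0 = mk(f$s0, ok), fit_r2 = mk(f$r2, ok),
         valid = valid_out, method = method,
         t2_bounds_ms = t2_bounds, offset = offset,
         drop_first_echo = drop_first_echo,
         n_valid = sum(valid_out), n_failed = length(idx) - sum(ok),
         echo_times_ms = stack$echo_times_ms),
    class = "t2_map"
  )
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("t2_map (%s): %d valid voxels, %d failed; T2 range %.2f-%.2f ms\n",
              x$method, x$n_valid, x$n_failed,
              min(x$t2_ms[x$valid]), max(x$t2_ms[x$valid])))
  invisible(x)
}
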