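#' Synthetic hindlimb phantom specification
#'
#' Parameters of the synthetic dystrophic-hindlimb phantom. `severity` in
#' \[0, 1\] drives both lesion load classes: diffuse mildly elevated T2
#' (edema-like, default 35 ms against a 25 ms healthy baseline) and focal
#' highly elevated T2 (necrosis/edema-like, default 65 ms). Areal lesion
#' fractions are monotone functions of severity (linear by default:
#' `0.40 * severity` mild, `0.12 * severity` high). Severity 0 produces a
#' lesion-free, healthy-muscle phantom.
#'
#' `snr` is the signal-to-noise ratio of healthy muscle on the first-echo
#' image: the two Gaussian noise channels of the Rician model have standard
#' deviation `s0_muscle * exp(-TE1 / t2_healthy_ms) / snr`. Use `snr = Inf`
#' to disable noise.
#'
#' @param seed Integer RNG seed controlling anatomy, lesion geometry and the
#'   default noise realization.
#' @param severity Real in \[0, 1\].
#' @param t2_healthy_ms,t2_lesion_mild_ms,t2_lesion_high_ms Tissue T2 values
#'   in ms; must be strictly increasing.
#' @param lesion_fraction_mild,lesion_fraction_high Functions mapping
#'   severity to the areal fraction of muscle covered by each lesion class;
#'   must be nondecreasing with values in \[0, 1\] and 0 at severity 0.
#' @param s0_muscle Proton-density amplitude of muscle (arbitrary units).
#' @param snr First-echo signal-to-noise ratio; `Inf` disables noise.
#' @param include_confounders Include non-muscle confounders: bone
#'   (low-signal discs), a skin/subcutaneous-fat rim (high-T2 ring) and a
#'   bladder (very high T2 blob).
#' @param lr_imbalance Left/right lesion imbalance in \[-1, 1\]; 0 (default)
#'   places lesions symmetrically in expectation.
#' @param edge_smooth_sigma Gaussian sigma (voxels) for optional soft lesion
#'   edges; 0 (default) keeps edges sharp so the ground-truth lesion burden
#'   equals the commanded areal fractions exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         severity = 0,
                         t2_healthy_ms = 25,
                         t2_lesion_mild_ms = 35,
                         t2_lesion_high_ms = 65,
                         lesion_fraction_mild = function(s) 0.40 * s,
                         lesion_fraction_high = function(s) 0.12 * s,
                         s0_muscle = 500,
                         snr = 50,
                         include_confounders = TRUE,
                         lr_imbalance = 0,
                         edge_smooth_sigma = 0) {
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("invalid parameter: severity must be in [0, 1]")
  }
  if (!(t2_healthy_ms < t2_lesion_mild_ms && t2_lesion_mild_ms < t2_lesion_high_ms)) {
    stop("invalid parameter: require t2_healthy_ms < t2_lesion_mild_ms < t2_lesion_high_ms")
  }
  if (is.na(snr) || snr <= 0) stop("invalid parameter: snr must be > 0 (Inf disables noise)")
  if (s0_muscle <= 0) stop("invalid parameter: s0_muscle must be > 0")
  if (abs(lr_imbalance) > 1) stop("invalid parameter: lr_imbalance must be in [-1, 1]")
  sgrid <- seq(0, 1, length.out = 21)
  for (f in list(lesion_fraction_mild, lesion_fraction_high)) {
    v <- vapply(sgrid, f, numeric(1))
    if (any(v < 0) || any(v > 1) || any(diff(v) < -1e-12)) {
      stop("invalid parameter: lesion fractions must be in [0, 1] and nondecreasing in severity")
    }
  }
  if (lesion_fraction_mild(0) != 0 || lesion_fraction_high(0) != 0) {
    stop("invalid parameter: lesion fractions must be 0 at severity 0")
  }
  if (lesion_fraction_mild(1) + lesion_fraction_high(1) >= 1) {
    stop("invalid parameter: total lesion fraction at severity 1 must be < 1")
  }
  structure(
    list(seed = as.integer(seed), severity = severity,
         t2_healthy_ms = t2_healthy_ms,
         t2_lesion_mild_ms = t2_lesion_mild_ms,
         t2_lesion_high_ms = t2_lesion_high_ms,
         lesion_fraction_mild = lesion_fraction_mild,
         lesion_fraction_high = lesion_fraction_high,
         s0_muscle = s0_muscle, snr = snr,
         include_confounders = isTRUE(include_confounders),
         lr_imbalance = lr_imbalance,
         edge_smooth_sigma = edge_smooth_sigma),
    class = "phantom_spec"
  )
}

# Fixed non-muscle tissue parameters (relative to s0_muscle).
.tissue_pars <- list(
  bone    = list(t2 = 10,  s0 = 0.05),
  rim     = list(t2 = 120, s0 = 0.90),
  bladder = list(t2 = 200, s0 = 1.10)
)

# Rasterized anatomy: label array (0 bg, 1 muscle, 2 bone, 3 fat/skin rim,
# 4 bladder) for one phantom. Two limb ellipses with a slight through-slice
# taper, central bone discs, a thin rim, and a bladder blob above the limbs.
.build_anatomy <- function(acq, include_confounders = TRUE) {
  R <- acq$matrix_size[1]; C <- acq$matrix_size[2]; S <- acq$n_slices
  rowm <- matrix(seq_len(R), R, C)
  colm <- matrix(seq_len(C), R, C, byrow = TRUE)
  labels <- array(0L, dim = c(R, C, S))
  mid <- (S + 1) / 2
  for (s in seq_len(S)) {
    f <- if (S > 1) 1 - 0.06 * abs(s - mid) / ((S - 1) / 2) else 1
    sl <- matrix(0L, R, C)
    for (cc in c(0.30, 0.70)) {
      cr <- 0.52 * R; ccol <- cc * C
      ar <- 0.26 * R * f; acol <- 0.17 * C * f
      inner <- ((rowm - cr) / ar)^2 + ((colm - ccol) / acol)^2 <= 1
      sl[inner] <- 1L
      if (include_confounders) {
        outer_e <- ((rowm - cr) / (1.12 * ar))^2 + ((colm - ccol) / (1.12 * acol))^2 <= 1
        sl[outer_e & !inner & sl == 0L] <- 3L
        rb <- max(1.5, 0.035 * R * f)
        bone <- (rowm - cr)^2 + (colm - ccol)^2 <= rb^2
        sl[bone] <- 2L
      }
    }
    if (include_confounders) {
      rb <- 0.07 * R * f
      blad <- (rowm - 0.28 * R)^2 + (colm - 0.50 * C)^2 <= rb^2
      sl[blad & sl == 0L] <- 4L
    }
    labels[, , s] <- sl
  }
  labels
}

# Draw random elliptical blobs over the candidate voxel set of one slice
# until exactly n_target voxels are covered (overshoot of the last blob is
# trimmed at random -- blob rasterization detail). Returns linear indices
# into the slice matrix.
.place_blobs <- function(candidates, rowm, colm, n_target, dims, lr_w = NULL) {
  covered <- integer(0)
  if (n_target <= 0 || length(candidates) == 0) return(covered)
  remaining <- candidates
  ax_max <- max(3, 0.12 * min(dims))
  ax_min <- max(1.2, 0.02 * min(dims))
  attempts <- 0L
  while (length(covered) < n_target && attempts < 2000L && length(remaining) > 0) {
    attempts <- attempts + 1L
    ci <- if (is.null(lr_w)) {
      remaining[sample.int(length(remaining), 1)]
    } else {
      remaining[sample.int(length(remaining), 1, prob = lr_w[remaining])]
    }
    cr <- rowm[ci]; ccol <- colm[ci]
    a <- stats::runif(1, ax_min, ax_max)
    b <- stats::runif(1, ax_min, ax_max)
    th <- stats::runif(1, 0, pi)
    dr <- rowm[remaining] - cr; dc <- colm[remaining] - ccol
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    new <- remaining[(u / a)^2 + (v / b)^2 <= 1]
    if (length(new) == 0) next
    need <- n_target - length(covered)
    if (length(new) > need) new <- new[sample.int(length(new), need)]
    covered <- c(covered, new)
    remaining <- setdiff(remaining, new)
  }
  covered
}

# Separable Gaussian blur of a 2-D matrix (reflected edges); used only for
# optional soft lesion edges.
.gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(r)]), x, rev(x[(n - r + 1):n]))
    stats::filter(xp, k, sides = 2)[(r + 1):(r + n)]
  }
  m1 <- apply(m, 2, pad_conv)
  t(apply(t(m1), 2, pad_conv))
}

# Noise-free phantom: ground-truth T2 and S0 fields plus anatomy labels.
# All randomness (anatomy-independent lesion geometry) comes from the
# caller's RNG state.
.phantom_fields <- function(spec, acq) {
  labels <- .build_anatomy(acq, spec$include_confounders)
  R <- dim(labels)[1]; C <- dim(labels)[2]; S <- dim(labels)[3]
  rowm <- matrix(seq_len(R), R, C)
  colm <- matrix(seq_len(C), R, C, byrow = TRUE)
  t2 <- array(0, dim = dim(labels))
  s0 <- array(0, dim = dim(labels))
  t2[labels == 1L] <- spec$t2_healthy_ms
  s0[labels == 1L] <- spec$s0_muscle
  for (nm in names(.tissue_pars)) {
    code <- c(bone = 2L, rim = 3L, bladder = 4L)[[nm]]
    t2[labels == code] <- .tissue_pars[[nm]]$t2
    s0[labels == code] <- .tissue_pars[[nm]]$s0 * spec$s0_muscle
  }
  frac_high <- spec$lesion_fraction_high(spec$severity)
  frac_mild <- spec$lesion_fraction_mild(spec$severity)
  lr_w <- NULL
  if (spec$lr_imbalance != 0) {
    lr_w <- matrix(1, R, C)
    lr_w[colm > C / 2] <- 1 + spec$lr_imbalance
    lr_w[colm <= C / 2] <- 1 - spec$lr_imbalance
    lr_w <- pmax(as.vector(lr_w), 1e-6)
  }
  for (s in seq_len(S)) {
    msl <- which(labels[, , s] == 1L)
    n_mus <- length(msl)
    if (n_mus == 0) next
    t2sl <- t2[, , s]
    idx_high <- .place_blobs(msl, rowm, colm, round(frac_high * n_mus),
                             c(R, C), lr_w)
    idx_mild <- .place_blobs(setdiff(msl, idx_high), rowm, colm,
                             round(frac_mild * n_mus), c(R, C), lr_w)
    t2sl[idx_high] <- spec$t2_lesion_high_ms
    t2sl[idx_mild] <- spec$t2_lesion_mild_ms
    if (spec$edge_smooth_sigma > 0) {
      sm <- .gauss_blur2d(t2sl, spec$edge_smooth_sigma)
      t2sl[msl] <- sm[msl]   # soften only inside muscle
    }
    t2[, , s] <- t2sl
  }
  mask_true <- labels == 1L
  burden <- if (any(mask_true)) {
    mean(t2[mask_true] > spec$t2_healthy_ms)
  } else 0
  list(t2 = t2, s0 = s0, labels = labels, mask_true = mask_true,
       lesion_burden = burden)
}

# Noiseless forward model S(TE) = S0 * exp(-TE / T2) as a 4-D array.
.forward_signal <- function(t2, s0, echo_times_ms) {
  d <- dim(t2)
  ne <- length(echo_times_ms)
  sig <- array(0, dim = c(d, ne))
  live <- t2 > 0
  for (e in seq_len(ne)) {
    v <- array(0, dim = d)
    v[live] <- s0[live] * exp(-echo_times_ms[e] / t2[live])
    sig[, , , e] <- v
  }
  sig
}

# Rician magnitude noise: two independent Gaussian channels of sd sigma.
.add_rician <- function(signal, sigma) {
  n <- length(signal)
  g1 <- array(stats::rnorm(n, 0, sigma), dim = dim(signal))
  g2 <- array(stats::rnorm(n, 0, sigma), dim = dim(signal))
  sqrt((signal + g1)^2 + g2^2)
}

.noise_sigma <- function(spec, acq) {
  if (is.infinite(spec$snr)) return(0)
  spec$s0_muscle * exp(-acq$echo_times_ms[1] / spec$t2_healthy_ms) / spec$snr
}

#' Generate a synthetic multi-echo hindlimb phantom
#'
#' Builds a noiseless multi-echo signal from per-voxel ground-truth T2 and
#' proton density via the monoexponential decay model
#' `S(TE) = S0 * exp(-TE / T2)`, then applies Rician magnitude noise
#' (two independent Gaussian channels, magnitude taken). Deterministic for a
#' given `spec$seed` (anatomy and lesions) and noise seed.
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acq_params()].
#' @param noise_seed Optional integer seed for the noise realization only;
#'   defaults to a substream derived from `spec$seed` so that the whole
#'   phantom is reproducible from the spec alone.
#' @return A list with elements `stack` (an [echo_stack()]) and `truth`
#'   (class `ground_truth`: `t2_field_ms`, `mask_true`, `lesion_burden`,
#'   `severity`).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 1, severity = 0.5, snr = Inf),
#'                    acq_params(matrix_size = c(48, 48), n_slices = 2))
#' ph$truth$lesion_burden
#' @export
make_phantom <- function(spec, acq = acq_params(), noise_seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acq_params"))
  sub <- withr::with_seed(spec$seed, sample.int(.Machine$integer.max - 1, 2))
  fields <- withr::with_seed(sub[1], .phantom_fields(spec, acq))
  signal <- .forward_signal(fields$t2, fields$s0, acq$echo_times_ms)
  sigma <- .noise_sigma(spec, acq)
  if (sigma > 0) {
    ns <- if (is.null(noise_seed)) sub[2] else as.integer(noise_seed)
    signal <- withr::with_seed(ns, .add_rician(signal, sigma))
  }
  truth <- structure(
    list(t2_field_ms = fields$t2, mask_true = fields$mask_true,
         lesion_burden = fields$lesion_burden, severity = spec$severity),
    class = "ground_truth"
  )
  list(stack = echo_stack(signal, acq$echo_times_ms, voxel_dims(acq),
                          acq$tr_ms),
       truth = truth)
}

#' Generate a test--retest phantom pair
#'
#' Two echo stacks sharing one anatomy, lesion field and ground truth but
#' with independent noise realizations, emulating re-imaging an animal a few
#' days after its first session. Optionally applies a small rigid in-plane
#' integer-voxel shift to the second member to mimic repositioning (off by
#' default).
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acq_params()].
#' @param seed_a,seed_b Distinct integer noise seeds for the two sessions.
#' @param shift_vox Integer (rows, cols) in-plane shift of the second
#'   member's anatomy before noise; default `c(0, 0)`.
#' @return List with `stack_a`, `stack_b` (both [echo_stack()]) and the
#'   shared `truth`.
#' @export
make_retest_pair <- function(spec, acq = acq_params(), seed_a, seed_b,
                             shift_vox = c(0L, 0L)) {
  if (identical(as.integer(seed_a), as.integer(seed_b))) {
    stop("invalid parameter: seed_a and seed_b must differ")
  }
  sub <- withr::with_seed(spec$seed, sample.int(.Machine$integer.max - 1, 2))
  fields <- withr::with_seed(sub[1], .phantom_fields(spec, acq))
  clean <- .forward_signal(fields$t2, fields$s0, acq$echo_times_ms)
  clean_b <- clean
  shift_vox <- as.integer(shift_vox)
  if (any(shift_vox != 0L)) {
    d <- dim(clean)
    shifted <- array(0, dim = d)
    r_src <- seq_len(d[1]) - shift_vox[1]
    c_src <- seq_len(d[2]) - shift_vox[2]
    ok_r <- r_src >= 1 & r_src <= d[1]
    ok_c <- c_src >= 1 & c_src <= d[2]
    shifted[which(ok_r), which(ok_c), , ] <- clean[r_src[ok_r], c_src[ok_c], , ]
    clean_b <- shifted
  }
  sigma <- .noise_sigma(spec, acq)
  sa <- clean; sb <- clean_b
  if (sigma > 0) {
    sa <- withr::with_seed(as.integer(seed_a), .add_rician(clean, sigma))
    sb <- withr::with_seed(as.integer(seed_b), .add_rician(clean_b, sigma))
  }
  truth <- structure(
    list(t2_field_ms = fields$t2, mask_true = fields$mask_true,
         lesion_burden = fields$lesion_burden, severity = spec$severity),
    class = "ground_truth"
  )
  vd <- voxel_dims(acq)
  list(stack_a = echo_stack(sa, acq$echo_times_ms, vd, acq$tr_ms),
       stack_b = echo_stack(sb, acq$echo_times_ms, vd, acq$tr_ms),
       truth = truth)
}

#' Synthetic cohort specification
#'
#' Group sizes and per-genotype severity distributions for a simulated
#' cohort, plus the parameters of the simulated Evans-blue-dye uptake
#' surrogate `dye = intercept + slope * lesion_burden + N(0, dye_noise_sd)`.
#' Defaults mirror a wildtype / mild-dystrophic / severe-dystrophic design:
#' WT severity fixed at 0, mdxB10 uniform on \[0.1, 0.8\] (wide inter-animal
#' spread), mdxD2 uniform on \[0.7, 1.0\]. Default group sizes (5/4/3) match
#' a small dye-validation cohort.
#'
#' @param n_per_group Named integer vector of animals per genotype; names
#'   from `WT`, `mdxB10`, `mdxD2` (others allowed, severity range required).
#' @param severity_ranges Named list of `c(lo, hi)` severity ranges.
#' @param dye_intercept,dye_slope,dye_noise_sd Dye-surrogate parameters
#'   (arbitrary optical-density units per mg); `dye_noise_sd >= 0`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(WT = 5L, mdxB10 = 4L, mdxD2 = 3L),
                        severity_ranges = list(WT = c(0, 0),
                                               mdxB10 = c(0.1, 0.8),
                                               mdxD2 = c(0.7, 1.0)),
                        dye_intercept = 0.1,
                        dye_slope = 2,
                        dye_noise_sd = 0.05) {
  if (dye_noise_sd < 0) stop("invalid parameter: dye_noise_sd must be >= 0")
  if (any(n_per_group < 0)) stop("invalid parameter: group sizes must be >= 0")
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("invalid parameter: n_per_group must be named by genotype")
  }
  missing_rng <- setdiff(names(n_per_group), names(severity_ranges))
  if (length(missing_rng)) {
    stop("invalid parameter: no severity range for group(s) ",
         paste(missing_rng, collapse = ", "))
  }
  structure(
    list(n_per_group = n_per_group, severity_ranges = severity_ranges,
         dye_intercept = dye_intercept, dye_slope = dye_slope,
         dye_noise_sd = dye_noise_sd),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of phantoms with dye-uptake surrogates
#'
#' One phantom per animal with severity drawn from its genotype's range and
#' a simulated dye uptake linear in the true lesion burden. Reproducible
#' given `seed`. With `imaging = FALSE` only the record table is produced
#' and the lesion burden is the analytic areal fraction
#' `lesion_fraction_mild(s) + lesion_fraction_high(s)` (which the voxelized
#' phantom matches up to per-slice rounding); this is orders of magnitude
#' faster for statistical simulations that do not need images.
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acq_params()] (used when `imaging = TRUE`).
#' @param seed Integer seed.
#' @param imaging Generate echo stacks (`TRUE`) or records only (`FALSE`).
#' @param phantom_args Named list of extra arguments passed to
#'   [phantom_spec()] for every animal (e.g. `snr`).
#' @return List with `records` (data.frame: animal_id, genotype, session,
#'   severity_true, lesion_burden, dye_uptake) and `phantoms` (list of
#'   [make_phantom()] results, or `NULL` when `imaging = FALSE`).
#' @export
make_cohort <- function(spec = cohort_spec(), acq = acq_params(), seed = 1L,
                        imaging = TRUE, phantom_args = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  total <- sum(spec$n_per_group)
  draws <- withr::with_seed(as.integer(seed), {
    sev <- unlist(lapply(names(spec$n_per_group), function(g) {
      n <- spec$n_per_group[[g]]
      if (n == 0) return(numeric(0))
      r <- spec$severity_ranges[[g]]
      stats::runif(n, r[1], r[2])
    }))
    list(severity = sev,
         phantom_seeds = sample.int(.Machine$integer.max - 1, total),
         dye_eps = stats::rnorm(total, 0, spec$dye_noise_sd))
  })
  genotype <- rep(names(spec$n_per_group), times = spec$n_per_group)
  animal_id <- unlist(lapply(names(spec$n_per_group), function(g) {
    sprintf("%s_%02d", g, seq_len(spec$n_per_group[[g]]))
  }))
  phantoms <- NULL
  template <- do.call(phantom_spec, c(list(seed = 1L), phantom_args))
  if (imaging) {
    phantoms <- vector("list", total)
    burden <- numeric(total)
    for (i in seq_len(total)) {
      psp <- do.call(phantom_spec,
                     c(list(seed = draws$phantom_seeds[i],
                            severity = draws$severity[i]),
                       phantom_args))
      phantoms[[i]] <- make_phantom(psp, acq)
      burden[i] <- phantoms[[i]]$truth$lesion_burden
    }
  } else {
    burden <- template$lesion_fraction_mild(draws$severity) +
      template$lesion_fraction_high(draws$severity)
  }
  records <- data.frame(
    animal_id = animal_id,
    genotype = genotype,
    session = 1L,
    severity_true = draws$severity,
    lesion_burden = burden,
    dye_uptake = spec$dye_intercept + spec$dye_slope * burden + draws$dye_eps,
    stringsAsFactors = FALSE
  )
  list(records = records, phantoms = phantoms)
}
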