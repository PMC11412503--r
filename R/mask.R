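#' Binary muscle mask with per-slice exclusions
#'
#' A 3-D binary label volume aligned to an echo stack's spatial axes plus a
#' set of excluded slice indices (1-based, third spatial axis). Any nonzero
#' voxel is treated as muscle; values outside \{0, 1\} trigger a warning.
#'
#' @param labels 3-D array (numeric or logical).
#' @param excluded_slices Integer vector of excluded slice indices.
#' @return Object of class `muscle_mask`.
#' @export
muscle_mask <- function(labels, excluded_slices = integer(0)) {
  if (length(dim(labels)) != 3) {
    stop("dimension error: mask labels must be a 3-D array")
  }
  lv <- as.vector(labels)
  if (!all(lv %in% c(0, 1))) {
    warning("mask contains values outside {0, 1}; treating any nonzero voxel as muscle")
  }
  lab <- array(labels != 0, dim = dim(labels))
  excluded_slices <- sort(unique(as.integer(excluded_slices)))
  if (length(excluded_slices) &&
      (min(excluded_slices) < 1 || max(excluded_slices) > dim(lab)[3])) {
    stop("invalid parameter: excluded slice index out of range")
  }
  structure(list(labels = lab, excluded_slices = excluded_slices),
            class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  cat(sprintf("muscle_mask: %s, %d muscle voxels, excluded slices: %s\n",
              paste(dim(x$labels), collapse = " x "), sum(x$labels),
              if (length(x$excluded_slices)) paste(x$excluded_slices, collapse = ",") else "none"))
  invisible(x)
}

#' Add slices to a mask's exclusion list
#'
#' Set semantics: excluding a slice twice is the same as once; excluding
#' nothing returns an identical mask.
#'
#' @param mask A [muscle_mask()].
#' @param slices Integer slice indices to exclude (1-based).
#' @return The mask with an updated exclusion set.
#' @export
exclude_slices <- function(mask, slices) {
  stopifnot(inherits(mask, "muscle_mask"))
  slices <- as.integer(slices)
  if (length(slices) && (min(slices) < 1 || max(slices) > dim(mask$labels)[3])) {
    stop("invalid parameter: slice index out of range")
  }
  muscle_mask(mask$labels, c(mask$excluded_slices, slices))
}

#' Apply a muscle mask to an echo stack
#'
#' Produces a masked view in which only mask-true voxels on non-excluded
#' slices are valid. The count of valid voxels equals the count of mask-true
#' voxels on non-excluded slices.
#'
#' @param stack An [echo_stack()].
#' @param mask A [muscle_mask()] sharing the stack's spatial grid.
#' @return Object of class `masked_stack`: `data`, `echo_times_ms`, `valid`
#'   (3-D logical), `n_valid`.
#' @export
apply_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "echo_stack"), inherits(mask, "muscle_mask"))
  if (!identical(dim(stack$data)[1:3], dim(mask$labels))) {
    stop("shape mismatch: mask and stack spatial dimensions differ")
  }
  valid <- mask$labels
  if (length(mask$excluded_slices)) valid[, , mask$excluded_slices] <- FALSE
  structure(list(data = stack$data, echo_times_ms = stack$echo_times_ms,
                 valid = valid, n_valid = sum(valid)),
            class = "masked_stack")
}

# --- small binary-image toolbox (3x3 cross structuring element) ----------

.shift2d <- function(m, dr, dc) {
  R <- nrow(m); C <- ncol(m)
  out <- matrix(FALSE, R, C)
  rs <- seq_len(R) - dr; cs <- seq_len(C) - dc
  ok_r <- rs >= 1 & rs <= R; ok_c <- cs >= 1 & cs <= C
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  out
}

.dilate2d <- function(m) {
  m | .shift2d(m, 1, 0) | .shift2d(m, -1, 0) | .shift2d(m, 0, 1) | .shift2d(m, 0, -1)
}

.erode2d <- function(m) {
  m & .shift2d(m, 1, 0) & .shift2d(m, -1, 0) & .shift2d(m, 0, 1) & .shift2d(m, 0, -1)
}

.open2d <- function(m) .dilate2d(.erode2d(m))
.close2d <- function(m) .erode2d(.dilate2d(m))

# 4-connected component labeling of a logical matrix (BFS).
.label_components <- function(m) {
  R <- nrow(m); C <- ncol(m)
  lab <- matrix(0L, R, C)
  nxt <- 0L
  idx_fg <- which(m)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (i in cur) {
        r <- ((i - 1L) %% R) + 1L
        cc <- ((i - 1L) %/% R) + 1L
        nb <- c(if (r > 1L) i - 1L, if (r < R) i + 1L,
                if (cc > 1L) i - R, if (cc < C) i + R)
        nb <- nb[m[nb] & lab[nb] == 0L]
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Otsu threshold on a numeric vector (256-bin histogram).
.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Automatic phantom muscle mask
#'
#' A simple stand-in for a trained segmentation network, adequate for
#' phantom-like contrast (muscle bright on the first echo, background dark):
#' Otsu threshold on the first echo, removal of long-T2 confounders
#' (skin/fat rim, bladder) by a two-echo rough T2 estimate, morphological
#' opening and closing, and removal of small connected components. The
#' returned mask is a subset of nonzero-signal voxels.
#'
#' @param stack An [echo_stack()].
#' @param t2_cutoff_ms Voxels with rough T2 above this are treated as
#'   non-muscle confounders (default 100 ms).
#' @param min_component Minimum 2-D connected-component size kept per slice;
#'   default scales with the matrix (`max(9, 5e-4 * rows * cols)`).
#' @return A [muscle_mask()] with no excluded slices.
#' @export
auto_mask_phantom <- function(stack, t2_cutoff_ms = 100, min_component = NULL) {
  stopifnot(inherits(stack, "echo_stack"))
  d <- dim(stack$data)
  if (is.null(min_component)) min_component <- max(9, round(5e-4 * d[1] * d[2]))
  first <- stack$data[, , , 1, drop = TRUE]
  if (length(dim(first)) < 3) dim(first) <- d[1:3]
  th <- .otsu(as.vector(first))
  fg <- first > th
  if (!any(fg)) stop("empty foreground: no voxels above the Otsu threshold")
  te <- stack$echo_times_ms
  k <- which.min(abs(te - (te[1] + 36)))
  if (k == 1) k <- min(2L, length(te))
  sk <- stack$data[, , , k, drop = TRUE]
  if (length(dim(sk)) < 3) dim(sk) <- d[1:3]
  rough <- (te[k] - te[1]) / log(pmax(first, 1e-12) / pmax(sk, 1e-12))
  keep <- fg & is.finite(rough) & rough > 0 & rough <= t2_cutoff_ms
  out <- array(FALSE, dim = d[1:3])
  for (s in seq_len(d[3])) {
    m <- .close2d(.open2d(keep[, , s]))
    lab <- .label_components(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0L])
      m <- m & matrix(sizes[pmax(lab, 1L)] >= min_component & lab > 0L,
                      d[1], d[2])
    }
    out[, , s] <- m & (first[, , s] > 0)
  }
  if (!any(out)) stop("empty foreground: no muscle-like component survived")
  muscle_mask(out)
}

#' Jaccard index between two binary masks
#'
#' Intersection over union of two binary volumes of identical shape.
#'
#' @param a,b Logical/binary arrays of identical dimension.
#' @return Scalar in \[0, 1\] (1 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
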