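#' Multi-slice multi-echo acquisition parameters
#'
#' Describes the spin-echo (MSME) acquisition that produced (or, for
#' phantoms, is being emulated by) an echo stack. Defaults emulate a 9.4T
#' small-animal hindlimb protocol: TR 4000 ms, 30 echoes at 9 ms spacing
#' (TE 9--270 ms), 256 x 256 matrix, 5 slices of 1 mm over a 35 x 35 mm
#' field of view.
#'
#' @param tr_ms Repetition time in ms.
#' @param echo_times_ms Strictly increasing vector of echo times in ms.
#' @param matrix_size Integer pair (rows, cols) of the in-plane matrix.
#' @param n_slices Number of axial slices.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param fov_mm Field of view (height, width) in mm.
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' range(acq$echo_times_ms)
#' @export
acq_params <- function(tr_ms = 4000,
                       echo_times_ms = seq(9, by = 9, length.out = 30),
                       matrix_size = c(256L, 256L),
                       n_slices = 5L,
                       slice_thickness_mm = 1,
                       fov_mm = c(35, 35)) {
  echo_times_ms <- as.numeric(echo_times_ms)
  if (length(echo_times_ms) == 0) {
    stop("invalid parameter: echo_times_ms must be non-empty")
  }
  if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0)) {
    stop("invalid parameter: echo_times_ms must be strictly increasing and > 0")
  }
  matrix_size <- as.integer(matrix_size)
  stopifnot(length(matrix_size) == 2, all(matrix_size >= 8),
            tr_ms > 0, n_slices >= 1, slice_thickness_mm > 0,
            length(fov_mm) == 2, all(fov_mm > 0))
  structure(
    list(tr_ms = tr_ms,
         echo_times_ms = echo_times_ms,
         matrix_size = matrix_size,
         n_slices = as.integer(n_slices),
         slice_thickness_mm = slice_thickness_mm,
         fov_mm = as.numeric(fov_mm)),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("MSME acquisition: TR %g ms, %d echoes (TE %g-%g ms), %d x %d, %d slices\n",
              x$tr_ms, length(x$echo_times_ms), min(x$echo_times_ms),
              max(x$echo_times_ms), x$matrix_size[1], x$matrix_size[2],
              x$n_slices))
  invisible(x)
}

#' Voxel dimensions implied by an acquisition
#'
#' @param acq An `acq_params` object.
#' @return Numeric (dy, dx, dz) in mm.
#' @export
voxel_dims <- function(acq) {
  c(acq$fov_mm[1] / acq$matrix_size[1],
    acq$fov_mm[2] / acq$matrix_size[2],
    acq$slice_thickness_mm)
}

#' Multi-echo image stack
#'
#' Container for a 4-D (row, col, slice, echo) magnitude image with its echo
#' times. All intensities must be finite and nonnegative; the echo axis must
#' match the echo-time vector.
#'
#' @param data 4-D nonnegative numeric array indexed (row, col, slice, echo).
#' @param echo_times_ms Strictly increasing echo times in ms, one per echo.
#' @param voxel_dims_mm Voxel dimensions (dy, dx, dz) in mm.
#' @param tr_ms Optional repetition time in ms.
#' @return An object of class `echo_stack`.
#' @export
echo_stack <- function(data, echo_times_ms, voxel_dims_mm = c(1, 1, 1),
                       tr_ms = NA_real_) {
  if (length(dim(data)) != 4) {
    stop("dimension error: echo stack data must be a 4-D array (row, col, slice, echo)")
  }
  echo_times_ms <- as.numeric(echo_times_ms)
  if (dim(data)[4] != length(echo_times_ms)) {
    stop("dimension error: echo axis length must equal length(echo_times_ms)")
  }
  if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0)) {
    stop("invalid parameter: echo_times_ms must be strictly increasing and > 0")
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("invalid data: intensities must be finite and >= 0")
  }
  structure(
    list(data = data, echo_times_ms = echo_times_ms,
         voxel_dims_mm = as.numeric(voxel_dims_mm), tr_ms = tr_ms),
    class = "echo_stack"
  )
}

#' @export
print.echo_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("echo_stack: %d x %d, %d slices, %d echoes (TE %g-%g ms)\n",
              d[1], d[2], d[3], d[4], min(x$echo_times_ms), max(x$echo_times_ms)))
  invisible(x)
}
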