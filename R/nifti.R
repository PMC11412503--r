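# Minimal single-file NIfTI-1 (.nii) I/O in base R. Little-endian only,
# datatypes uint8/int16/int32/float32/float64, no extensions. The installed
# stack has no NIfTI package, so this is deliberately small and round-trip
# exact for float64.

.nifti_dtypes <- data.frame(
  name = c("uint8", "int16", "int32", "float32", "float64"),
  code = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

.pad_raw <- function(s, n) {
  r <- charToRaw(if (is.null(s) || is.na(s)) "" else s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

#' Write a numeric array as a NIfTI-1 file
#'
#' @param data Numeric or logical array, 1--7 dimensions.
#' @param path Output path (`.nii`, uncompressed).
#' @param voxel_dims_mm Voxel sizes for the first three dimensions, in mm.
#' @param datatype One of `"float64"` (default; bit-exact for doubles),
#'   `"float32"`, `"int16"`, `"int32"`, `"uint8"`.
#' @param descrip Optional description string (<= 80 bytes).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, voxel_dims_mm = c(1, 1, 1),
                        datatype = "float64", descrip = "") {
  dt <- .nifti_dtypes[match(datatype, .nifti_dtypes$name), ]
  if (is.na(dt$code)) stop("unsupported datatype: ", datatype)
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) > 7) stop("dimension error: at most 7 dimensions supported")
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  pixdim <- rep(1, 8)
  pixdim[1] <- 1
  pixdim[2:4] <- c(voxel_dims_mm, rep(1, 3))[1:3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                          # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)  # data_type..dim_info
  wi(dim8, 2)                          # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)            # intent_p1..3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(pixdim)                           # pixdim[8] (pixdim[0] = qfac)
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)     # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                     # glmax, glmin
  writeBin(.pad_raw(descrip, 80), con)
  writeBin(raw(24), con)               # aux_file
  wi(0L, 2); wi(1L, 2)                 # qform_code, sform_code
  wf(rep(0, 6))                        # quatern_b..d, qoffset_x..z
  wf(c(pixdim[2], 0, 0, 0))            # srow_x
  wf(c(0, pixdim[3], 0, 0))            # srow_y
  wf(c(0, 0, pixdim[4], 0))            # srow_z
  writeBin(raw(16), con)               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                # extension flag
  v <- as.vector(data)
  if (dt$name == "float64") {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  } else if (dt$name == "float32") {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = dt$bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path Path to an uncompressed single-file `.nii`.
#' @return List with `data` (array), `pixdim` (voxel sizes, first three
#'   dims), `datatype` (name), `descrip`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")
  rf <- function(n, size = 4)
    readBin(con, "double", n = n, size = size, endian = "little")
  sizeof <- ri(1, 4)
  if (!identical(sizeof, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof, "): ", path)
  }
  readBin(con, "raw", n = 36)          # data_type..dim_info
  dim8 <- ri(8, 2)
  rf(3); ri(1, 2)                      # intent
  dcode <- ri(1, 2); ri(1, 2); ri(1, 2)  # datatype, bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", n = 2)
  rf(4); ri(2, 4)
  draw <- readBin(con, "raw", n = 80)
  nz <- which(draw == as.raw(0))
  descrip <- rawToChar(draw[seq_len(if (length(nz)) nz[1] - 1L else 80L)])
  readBin(con, "raw", n = 24)
  ri(2, 2); rf(6); rf(12)
  readBin(con, "raw", n = 16)
  mraw <- readBin(con, "raw", n = 4)
  magic <- rawToChar(mraw[seq_len(3)])
  if (!identical(magic, "n+1")) {
    stop("unsupported NIfTI variant (magic = ", magic,
         "); only single-file n+1 is supported")
  }
  dt <- .nifti_dtypes[match(dcode, .nifti_dtypes$code), ]
  if (is.na(dt$code)) stop("unsupported NIfTI datatype code: ", dcode)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  n <- prod(dims)
  seek(con, where = vox_offset, origin = "start")
  v <- switch(dt$name,
    uint8   = ri(n, 1, signed = FALSE),
    int16   = ri(n, 2),
    int32   = ri(n, 4),
    float32 = rf(n, 4),
    float64 = readBin(con, "double", n = n, size = 8, endian = "little"))
  if (length(v) != n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    v <- v * scl_slope + scl_inter
  }
  list(data = array(v, dim = dims), pixdim = pixdim[2:4][seq_len(min(3, ndim))],
       datatype = dt$name, descrip = descrip)
}

.sidecar_path <- function(path) {
  sub("\\.nii$", ".json", path)
}

#' Write an echo stack as NIfTI + JSON sidecar
#'
#' The 4-D magnitude data are written as float64 (bit-exact round trip); the
#' sidecar carries the echo times, TR, voxel dimensions and any extra
#' provenance fields.
#'
#' @param stack An [echo_stack()].
#' @param path Output `.nii` path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @param extra Named list of additional sidecar fields (e.g. seed, spec,
#'   config hash).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "echo_stack"))
  write_nifti(stack$data, path, voxel_dims_mm = stack$voxel_dims_mm,
              datatype = "float64", descrip = "multi-echo magnitude stack")
  side <- c(list(echo_times_ms = stack$echo_times_ms,
                 tr_ms = stack$tr_ms,
                 voxel_dims_mm = stack$voxel_dims_mm),
            extra)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an echo stack from NIfTI + JSON sidecar
#'
#' @param path Path to a 4-D `.nii` file.
#' @param echo_times_ms Optional explicit echo times; when `NULL` they are
#'   taken from the JSON sidecar, and a missing sidecar or missing
#'   `echo_times_ms` field is an error.
#' @return An [echo_stack()].
#' @export
read_stack <- function(path, echo_times_ms = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4) {
    stop("dimension error: expected a 4-D echo-indexed volume, got ",
         length(dim(nii$data)), "-D")
  }
  tr <- NA_real_
  if (is.null(echo_times_ms)) {
    sp <- .sidecar_path(path)
    if (!file.exists(sp)) {
      stop("missing sidecar ", sp, ": field 'echo_times_ms' unavailable")
    }
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(side$echo_times_ms)) {
      stop("sidecar ", sp, " is missing required field 'echo_times_ms'")
    }
    echo_times_ms <- as.numeric(side$echo_times_ms)
    if (!is.null(side$tr_ms)) tr <- as.numeric(side$tr_ms)
  }
  echo_stack(nii$data, echo_times_ms, voxel_dims_mm = nii$pixdim, tr_ms = tr)
}

#' Write / read a muscle mask as NIfTI + JSON sidecar
#'
#' Masks are stored as uint8 0/1 volumes; the excluded-slice list lives in
#' the sidecar (`{"excluded_slices": [...]}`, 1-based).
#'
#' @param mask A [muscle_mask()].
#' @param path Output `.nii` path.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, voxel_dims_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "muscle_mask"))
  write_nifti(array(as.integer(mask$labels), dim = dim(mask$labels)), path,
              voxel_dims_mm = voxel_dims_mm, datatype = "uint8",
              descrip = "muscle mask")
  jsonlite::write_json(list(excluded_slices = as.integer(mask$excluded_slices)),
                       .sidecar_path(path), auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3) {
    stop("dimension error: expected a 3-D mask volume")
  }
  excl <- integer(0)
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(side$excluded_slices)) excl <- as.integer(side$excluded_slices)
  }
  muscle_mask(nii$data, excluded_slices = excl)
}

#' Write a fitted T2 map with its fit report
#'
#' Writes the T2 volume (`<path>`), the S0 and R-squared volumes
#' (`<path minus .nii>_s0.nii`, `_r2.nii`; invalid voxels as NaN) and a JSON
#' fit report (`.json` sidecar) with voxel counts, method and bounds.
#'
#' @param map A `t2_map` from [fit_map()].
#' @param path Output `.nii` path for the T2 volume.
#' @param voxel_dims_mm Voxel dimensions in mm.
#' @param extra Named list merged into the JSON report.
#' @return Invisibly, `path`.
#' @export
write_t2_map <- function(map, path, voxel_dims_mm = c(1, 1, 1),
                         extra = list()) {
  stopifnot(inherits(map, "t2_map"))
  base <- sub("\\.nii$", "", path)
  nanify <- function(a) { a[!map$valid] <- NaN; a }
  write_nifti(nanify(map$t2_ms), path, voxel_dims_mm, "float64", "T2 map (ms)")
  write_nifti(nanify(map$s0), paste0(base, "_s0.nii"), voxel_dims_mm,
              "float64", "fitted S0")
  write_nifti(nanify(map$fit_r2), paste0(base, "_r2.nii"), voxel_dims_mm,
              "float64", "fit R-squared")
  report <- c(list(method = map$method, n_valid = sum(map$valid),
                   n_failed = map$n_failed,
                   t2_bounds_ms = map$t2_bounds_ms), extra)
  jsonlite::write_json(report, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
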