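# Minimal NIfTI-1 reader/writer.
#
# The deployment environment provides no R NIfTI package, so the format is
# handled here directly. Only the subset of NIfTI-1 needed for co-registered
# research volumes is supported: single-file .nii / .nii.gz, 3D grids,
# sform/qform affines, the common scalar datatypes, scl_slope/scl_inter
# rescaling. Written files always carry a valid sform (code 1) and are
# readable by nibabel and other standard tools.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

.open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.read_cstring <- function(raw_vec) {
  zero <- which(raw_vec == as.raw(0))
  n <- if (length(zero)) zero[1] - 1L else length(raw_vec)
  if (n == 0L) return("")
  rawToChar(raw_vec[seq_len(n)])
}

#' Read a NIfTI-1 header and image
#'
#' Internal workhorse behind [read_volume()] and [read_labelmap()]. Returns the
#' raw array and the voxel-to-world affine in RAS millimetres.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3D array) and `affine` (4x4 matrix).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .open_nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- .read_cstring(hdr_raw[345:348])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(idx, what, size, n = 1L, signed = TRUE) {
    readBin(hdr_raw[idx], what, n = n, size = size, endian = endian,
            signed = signed)
  }
  dim_field <- rd(41:56, "integer", 2L, n = 8L)
  datatype  <- rd(71:72, "integer", 2L)
  pixdim    <- rd(77:108, "double", 4L, n = 8L)
  vox_offset <- rd(109:112, "double", 4L)
  scl_slope  <- rd(113:116, "double", 4L)
  scl_inter  <- rd(117:120, "double", 4L)
  qform_code <- rd(253:254, "integer", 2L)
  sform_code <- rd(255:256, "integer", 2L)
  quatern    <- rd(257:268, "double", 4L, n = 3L)
  qoffset    <- rd(269:280, "double", 4L, n = 3L)
  srow       <- rbind(rd(281:296, "double", 4L, n = 4L),
                      rd(297:312, "double", 4L, n = 4L),
                      rd(313:328, "double", 4L, n = 4L))

  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0]: ", ndim)
  dims <- dim_field[seq(2L, 1L + ndim)]
  if (ndim > 3L) {
    if (any(dims[-(1:3)] > 1L)) stop("expected 3D volume, got ", ndim, "D image")
    dims <- dims[1:3]
  }
  if (length(dims) != 3L || any(dims <= 0L))
    stop("expected 3D volume with positive dimensions")

  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)

  nvox <- prod(dims)
  # skip any header extension up to vox_offset
  to_skip <- as.integer(round(vox_offset)) - 348L
  if (to_skip > 0L) readBin(con, "raw", n = to_skip)
  data <- readBin(con, spec$what, n = nvox, size = spec$size,
                  endian = endian, signed = spec$signed)
  if (length(data) < nvox) stop("truncated NIfTI image data in ", path)
  if (!(scl_slope %in% c(0, 1)) || scl_inter != 0) {
    slope <- if (scl_slope == 0) 1 else scl_slope
    data <- data * slope + scl_inter
  }
  data <- array(as.double(data), dim = dims)

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else if (qform_code > 0L) {
    affine <- .qform_to_affine(quatern, qoffset, pixdim)
  } else {
    affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4]
  }
  list(data = data, affine = affine)
}

.qform_to_affine <- function(quatern, qoffset, pixdim) {
  b <- quatern[1]; c <- quatern[2]; d <- quatern[3]
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - c * c - b * b
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  affine <- diag(4)
  affine[1:3, 1:3] <- R %*% S
  affine[1:3, 4] <- qoffset
  affine
}

#' Write a 3D array as a NIfTI-1 file
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (RAS, mm).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float64"` for intensity volumes or `"int16"` for label
#'   maps; label values must fit in a signed 16-bit integer.
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(data, affine, path, datatype = c("float64", "int16")) {
  datatype <- match.arg(datatype)
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  dims <- dim(data)
  dt_code <- if (datatype == "float64") 64L else 4L
  bitpix  <- if (datatype == "float64") 64L else 16L
  if (datatype == "int16") {
    rng <- range(data)
    if (rng[1] < -32768 || rng[2] > 32767)
      stop("label values exceed int16 range")
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- .open_nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                               # sizeof_hdr
  wraw(34L)                                  # data_type, db_name, extents, session_error
  writeBin(charToRaw("r"), con)              # regular
  wraw(1L)                                   # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)        # dim[8]
  wd(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, 2L)                                 # intent_code
  wi(dt_code, 2L)                            # datatype
  wi(bitpix, 2L)                             # bitpix
  wi(0L, 2L)                                 # slice_start
  wd(c(1, spacing, 1, 1, 1, 1))              # pixdim[8], qfac = 1
  wd(352)                                    # vox_offset
  wd(1); wd(0)                               # scl_slope, scl_inter
  wi(0L, 2L); wraw(1L)                       # slice_end, slice_code
  writeBin(as.raw(2L), con)                  # xyzt_units: mm
  wd(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                          # glmax, glmin
  wraw(80L); wraw(24L)                       # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                     # qform_code = 0, sform_code = 1
  wd(c(0, 0, 0)); wd(c(0, 0, 0))             # quatern, qoffset
  wd(affine[1, ]); wd(affine[2, ]); wd(affine[3, ])
  wraw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wraw(4L)                                   # extension flag

  if (datatype == "float64") {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(round(data)), con, size = 2L, endian = "little")
  }
  invisible(path)
}
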