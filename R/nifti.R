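# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available in the installed R stack, so this implements
# the small subset of the format the package needs: little-endian single-file
# volumes, datatypes uint8/int16/int32/float32/float64, pixdim spacing and an
# axis-aligned sform. Arrays are exposed in this package's (z, y, x) axis
# order; on disk NIfTI stores x fastest, so data are permuted on the way
# through. Anything fancier (qform rotations, extensions beyond the initial
# four bytes, big-endian files) is out of scope and rejected loudly.

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read and write NIfTI-1 volumes
#'
#' `write_nifti()` stores a [voxel_grid] (as float32) or a [nodule_mask]
#' (as uint8) as a single-file little-endian NIfTI-1 image, with spacing in
#' `pixdim` and an axis-aligned `sform` carrying the origin. `read_nifti()`
#' reads such a file back into a `voxel_grid`; `read_nifti_mask()` reads one
#' and binarises it (non-zero = foreground) into a `nodule_mask`.
#'
#' @param x a `voxel_grid` or `nodule_mask`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_nifti()` returns `path` invisibly; the readers return a
#'   `voxel_grid` / `nodule_mask`.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "nodule_mask")) {
    arr <- array(as.integer(x$mask), dim(x$mask))
    datatype <- 2L; bitpix <- 8L
    spacing <- x$spacing; origin <- x$origin
  } else if (inherits(x, "voxel_grid")) {
    arr <- x$values
    datatype <- 16L; bitpix <- 32L
    spacing <- x$spacing; origin <- x$origin
  } else stop("`x` must be a voxel_grid or nodule_mask", call. = FALSE)

  d <- dim(arr)                       # (z, y, x)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wint <- function(v, size) writeBin(as.integer(v), con, size = size,
                                     endian = "little")
  wflt <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wchr <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               raw(n - min(length(raw), n))), con)
  }

  wint(348L, 4)                       # sizeof_hdr
  wchr("", 10); wchr("", 18)          # data_type, db_name
  wint(0L, 4); wint(0L, 2)            # extents, session_error
  wchr("r", 1); wchr("", 1)           # regular, dim_info
  wint(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L), 2)     # dim: (x,y,z)
  wflt(c(0, 0, 0)); wint(0L, 2)       # intent_p1-3, intent_code
  wint(datatype, 2); wint(bitpix, 2); wint(0L, 2)      # datatype,bitpix,slice_start
  wflt(c(1, spacing[3], spacing[2], spacing[1], 1, 1, 1, 1))  # pixdim
  wflt(352); wflt(1); wflt(0)         # vox_offset, scl_slope, scl_inter
  wint(0L, 2); wchr("", 1); wchr("", 1)                # slice_end/code, xyzt_units
  wflt(c(0, 0, 0, 0)); wint(0L, 4); wint(0L, 4)        # cal/slice_dur/toffset/glmax/glmin
  wchr("ssngrowth", 80); wchr("", 24) # descrip, aux_file
  wint(0L, 2); wint(1L, 2)            # qform_code = 0, sform_code = 1
  wflt(c(0, 0, 0, 0, 0, 0))           # quatern b,c,d + qoffset
  wflt(c(spacing[3], 0, 0, origin[3]))                 # srow_x
  wflt(c(0, spacing[2], 0, origin[2]))                 # srow_y
  wflt(c(0, 0, spacing[1], origin[1]))                 # srow_z
  wchr("", 16)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)        # magic
  writeBin(raw(4), con)               # extension flag: none
  dat <- aperm(arr, c(3, 2, 1))       # to x-fastest
  if (datatype == 2L) {
    writeBin(as.raw(as.integer(dat)), con)
  } else {
    writeBin(as.numeric(dat), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path, call. = FALSE)
  rint <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rflt <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rint(0, 4) != 348L)
    stop(path, " is not a little-endian NIfTI-1 file", call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1")
    stop("unsupported NIfTI magic '", magic, "' (need single-file n+1)",
         call. = FALSE)
  dim0 <- rint(40, 2, 8)
  if (dim0[1] < 3) stop("need a 3D NIfTI volume", call. = FALSE)
  if (dim0[1] > 3 && any(dim0[5:(dim0[1] + 1)] > 1))
    stop("only single-frame 3D volumes are supported", call. = FALSE)
  nx <- dim0[2]; ny <- dim0[3]; nz <- dim0[4]
  datatype <- rint(70, 2)
  pixdim <- rflt(76, 8)
  vox_offset <- rflt(108)
  slope <- rflt(112); inter <- rflt(116)
  sform_code <- rint(254, 2)
  origin_xyz <- if (sform_code > 0) {
    c(rflt(280, 4)[4], rflt(296, 4)[4], rflt(312, 4)[4])
  } else c(0, 0, 0)

  seek(con, where = vox_offset, origin = "start")
  n <- nx * ny * nz
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (length(vals) < n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  arr <- aperm(array(vals, c(nx, ny, nz)), c(3, 2, 1))
  voxel_grid(arr, spacing = c(pixdim[4], pixdim[3], pixdim[2]),
             origin = c(origin_xyz[3], origin_xyz[2], origin_xyz[1]))
}

#' @rdname write_nifti
#' @export
read_nifti_mask <- function(path) {
  g <- read_nifti(path)
  nodule_mask(g$values != 0, spacing = g$spacing, origin = g$origin)
}
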