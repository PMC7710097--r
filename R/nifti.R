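# Minimal NIfTI-1 reader/writer.
#
# Scope: single-file .nii / .nii.gz, 3D images, datatypes uint8 / int16 /
# int32 / float32 / float64, scl_slope/scl_inter honoured, affine taken from
# the sform when present (method 3), else the qform quaternion (method 2),
# else pixdim on the diagonal (method 1). This is all the pipeline needs;
# anything else errors loudly rather than guessing.

.nifti_datatypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "double", "double"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

.read_nifti_header <- function(raw348, endian) {
  rd <- function(off, what, n, size) {
    readBin(raw348[(off + 1):length(raw348)], what = what, n = n,
            size = size, endian = endian, signed = TRUE)
  }
  list(
    sizeof_hdr = rd(0, "integer", 1, 4),
    dim        = rd(40, "integer", 8, 2),
    datatype   = rd(70, "integer", 1, 2),
    bitpix     = rd(72, "integer", 1, 2),
    pixdim     = rd(76, "double", 8, 4),
    vox_offset = rd(108, "double", 1, 4),
    scl_slope  = rd(112, "double", 1, 4),
    scl_inter  = rd(116, "double", 1, 4),
    qform_code = rd(252, "integer", 1, 2),
    sform_code = rd(254, "integer", 1, 2),
    quatern    = rd(256, "double", 3, 4),
    qoffset    = rd(268, "double", 3, 4),
    srow       = matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE),
    magic      = rawToChar(raw348[345:347])
  )
}

.nifti_affine <- function(hdr) {
  if (hdr$sform_code > 0L) {
    rbind(hdr$srow, c(0, 0, 0, 1))
  } else if (hdr$qform_code > 0L) {
    b <- hdr$quatern[1]; c_ <- hdr$quatern[2]; d <- hdr$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- if (a2 < 0) 0 else sqrt(a2)
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), nrow = 3, byrow = TRUE)
    qfac <- if (is.na(hdr$pixdim[1]) || hdr$pixdim[1] >= 0) 1 else -1
    sp <- hdr$pixdim[2:4]
    A <- R %*% diag(c(sp[1], sp[2], sp[3] * qfac))
    rbind(cbind(A, hdr$qoffset), c(0, 0, 0, 1))
  } else {
    A <- diag(4)
    diag(A)[1:3] <- hdr$pixdim[2:4]
    A
  }
}

#' @keywords internal
#' @noRd
read_nifti <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read NIfTI file: '", path, "' does not exist", call. = FALSE)
  }
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  raw348 <- readBin(con, "raw", n = 348)
  if (length(raw348) < 348) {
    stop("cannot read NIfTI file '", path, "': truncated header", call. = FALSE)
  }
  sz <- readBin(raw348, "integer", 1, 4, endian = "little")
  endian <- if (sz == 348L) "little" else "big"
  if (endian == "big" &&
      readBin(raw348, "integer", 1, 4, endian = "big") != 348L) {
    stop("'", path, "' is not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  hdr <- .read_nifti_header(raw348, endian)
  if (!hdr$magic %in% c("n+1", "ni1")) {
    stop("'", path, "' is not a NIfTI-1 file (bad magic '", hdr$magic, "')",
         call. = FALSE)
  }
  ndim <- hdr$dim[1]
  dims <- hdr$dim[2:(1 + max(ndim, 1))]
  if (ndim > 3L && any(hdr$dim[5:8] > 1L, na.rm = TRUE)) {
    stop("'", path, "' has ", ndim, " dimensions; only 3D volumes are supported",
         call. = FALSE)
  }
  dims <- hdr$dim[2:4]
  dims[dims < 1L] <- 1L
  dt <- .nifti_datatypes[.nifti_datatypes$code == hdr$datatype, ]
  if (nrow(dt) != 1L) {
    stop("unsupported NIfTI datatype code ", hdr$datatype, " in '", path, "'",
         call. = FALSE)
  }
  # skip to vox_offset (bytes already consumed: 348)
  skip <- round(hdr$vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                  endian = endian, signed = dt$signed)
  if (length(vals) < n) {
    stop("'", path, "': data truncated (expected ", n, " voxels)", call. = FALSE)
  }
  if (!is.na(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  }
  list(data = array(vals, dim = dims),
       spacing = abs(hdr$pixdim[2:4]),
       transform = .nifti_affine(hdr))
}

#' @keywords internal
#' @noRd
write_nifti <- function(data, spacing, transform, path, datatype = NULL) {
  dims <- dim(data)
  stopifnot(length(dims) == 3L)
  if (is.null(datatype)) {
    v <- as.vector(data)
    datatype <- if (all(v == round(v)) && min(v) >= 0 && max(v) <= 255) {
      2L                            # uint8: masks and label maps
    } else if (all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767) {
      4L
    } else 64L                      # float64: quantitative maps, lossless
  }
  dt <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wI <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wI(348L, 4); writeBin(raw(36), con)                       # sizeof_hdr + unused
  wI(c(3L, dims, 1L, 1L, 1L, 1L), 2)                        # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2)                                 # intent_p1-3, intent_code
  wI(datatype, 2); wI(dt$size * 8L, 2); wI(0L, 2)           # datatype, bitpix, slice_start
  wF(c(1, spacing, 1, 1, 1, 1))                             # pixdim[8], qfac=1
  wF(352); wF(1); wF(0)                                     # vox_offset, scl_slope, scl_inter
  writeBin(raw(3), con); wI(0L, 1)                          # slice_end/code, xyzt_units
  wF(c(0, 0, 0, 0))                                         # cal_max/min, slice_dur, toffset
  wI(c(0L, 0L), 4)                                          # glmax, glmin
  writeBin(raw(80 + 24), con)                               # descrip, aux_file
  wI(0L, 2); wI(2L, 2)                                      # qform_code=0, sform_code=2
  wF(c(0, 0, 0)); wF(c(0, 0, 0))                            # quatern, qoffset
  wF(t(transform[1:3, , drop = FALSE]))                     # srow_x/y/z
  writeBin(raw(16), con)                                    # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)    # magic
  writeBin(raw(4), con)                                     # extension flag
  storage <- if (dt$what == "integer") as.integer(data) else as.double(data)
  writeBin(storage, con, size = dt$size, endian = "little")
  invisible(path)
}
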