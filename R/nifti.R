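# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# Only the fields the pipeline needs are honored: dim, datatype, pixdim,
# scl_slope/inter, and the sform/qform affines (voxel index -> world RAS mm,
# 0-based indices as in the NIfTI standard).  No pre-installed R package
# provides NIfTI in this stack, hence this purpose-built reader/writer.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `affine` (4x4 voxel-index to world RAS
#'   mm transform, 0-based voxel indices), and `pixdim` (voxel sizes, mm).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd <- function(what, n, size, offset, signed = TRUE, endian = "little") {
    readBin(hdr[(offset + 1):length(hdr)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  sizeof_hdr <- rd("integer", 1, 4, 0)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd("integer", 1, 4, 0, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  dim0 <- rd("integer", 8, 2, 40, endian = endian)
  ndim <- dim0[1]
  dims <- dim0[2:(1 + max(ndim, 1))]
  datatype <- rd("integer", 1, 2, 70, endian = endian)
  pixdim <- rd("numeric", 8, 4, 76, endian = endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian = endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian = endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian = endian)
  qform_code <- rd("integer", 1, 2, 252, endian = endian)
  sform_code <- rd("integer", 1, 2, 254, endian = endian)
  quatern <- rd("numeric", 3, 4, 256, endian = endian)
  qoffset <- rd("numeric", 3, 4, 268, endian = endian)
  srow <- matrix(rd("numeric", 12, 4, 280, endian = endian),
                 nrow = 3, byrow = TRUE)

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  nvox <- prod(dims)
  # skip to vox_offset
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  data <- array(data, dim = dims)

  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
  } else if (qform_code > 0) {
    b <- quatern[1]; c_ <- quatern[2]; d <- quatern[3]
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- if (a2 < 0) 0 else sqrt(a2)
    R <- matrix(c(
      a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
      2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_
    ), nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sc <- c(pixdim[2], pixdim[3], qfac * pixdim[4])
    affine[1:3, 1:3] <- R %*% diag(sc)
    affine[1:3, 4] <- qoffset
  } else {
    affine[1:3, 1:3] <- diag(pixdim[2:4])
  }
  list(data = data, affine = affine, pixdim = abs(pixdim[2:(1 + min(ndim, 3))]))
}

#' Write a NIfTI-1 volume
#'
#' @param data Numeric or integer array (2D or 3D; 2D is stored with a
#'   singleton third dimension).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4x4 voxel-index to world transform (stored as sform).
#' @param datatype `"auto"`, `"uint8"`, `"int16"`, `"int32"`, `"float32"` or
#'   `"float64"`. `"auto"` picks int16 for integer-valued data, else float32.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "auto") {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stop("write_nifti supports 2D/3D arrays")
  vals <- as.vector(data)
  if (identical(datatype, "auto")) {
    intlike <- all(vals == round(vals)) && max(abs(vals)) < 32767
    datatype <- if (intlike) "int16" else "float32"
  }
  code <- switch(datatype,
    uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
    stop("unsupported datatype: ", datatype))
  dt <- NIFTI_DTYPES[[as.character(code)]]
  bitpix <- as.integer(dt$size * 8)

  dims <- dim(data)
  pix <- sqrt(colSums(affine[1:3, 1:3]^2))

  buf <- raw(348)
  poke <- function(buf, x, what, size, offset) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    buf[(offset + 1):(offset + length(b))] <- b
    buf
  }
  buf <- poke(buf, 348L, "integer", 4, 0)
  buf <- poke(buf, c(3L, dims, 1L, 1L, 1L, 1L), "integer", 2, 40)
  buf <- poke(buf, code, "integer", 2, 70)
  buf <- poke(buf, bitpix, "integer", 2, 72)
  buf <- poke(buf, c(1, pix, 1, 1, 1, 1), "numeric", 4, 76)
  buf <- poke(buf, 352, "numeric", 4, 108)          # vox_offset
  buf <- poke(buf, c(1, 0), "numeric", 4, 112)      # scl_slope/inter
  buf <- poke(buf, c(0L, 1L), "integer", 2, 252)    # qform=0, sform=1
  buf <- poke(buf, as.numeric(t(affine[1:3, ])), "numeric", 4, 280)
  magic <- charToRaw("n+1")
  buf[345:347] <- magic

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(buf, con)
  writeBin(raw(4), con)  # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
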