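#' @include AllClasses.R scan.R
NULL

# Minimal NIfTI-1 I/O (uncompressed .nii, native little-endian).  Scan
# volumes are written as float32; enough of the header is populated
# (dims, pixdim, units, magic) for standard viewers to read the files.

#' Write a scan series or volume as NIfTI-1
#'
#' @param x a \linkS4class{ScanSeries}, or a 3D/4D numeric array
#' @param path output path (.nii)
#' @param voxelSize,TR geometry when x is a bare array
#' @return the path, invisibly
#' @export
writeNifti <- function(x, path, voxelSize = c(3, 3, 8), TR = 2) {
  if (is(x, "ScanSeries")) {
    voxelSize <- x@voxelSize; TR <- x@TR; x <- x@data
  }
  d <- dim(x)
  .check(length(d) %in% c(3, 4), "need a 3D or 4D array")
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(v, size = 4L) writeBin(as.integer(v), con, size = size,
                                        endian = "little")
  wF <- function(v) writeBin(as.numeric(v), con, size = 4L,
                             endian = "little")
  wC <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wI(348)                         # sizeof_hdr
  wC("", 10); wC("", 18)          # data_type, db_name
  wI(0); wI(0, 2L); wC("r", 1); wC("", 1)  # extents..dim_info
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  wI(dim8, 2L)
  wF(c(0, 0, 0)); wI(0, 2L)       # intent
  wI(16, 2L); wI(32, 2L); wI(0, 2L)  # datatype float32, bitpix, slice_start
  wF(c(1, voxelSize, TR, 0, 0, 0))   # pixdim (qfac first)
  wF(352)                         # vox_offset
  wF(1); wF(0)                    # scl_slope, scl_inter
  wI(0, 2L); wC("", 1)            # slice_end, slice_code
  writeBin(as.raw(10L), con)      # xyzt_units: mm | sec
  wF(0); wF(0); wF(0); wF(0)      # cal_max/min, slice_duration, toffset
  wI(0); wI(0)                    # glmax, glmin
  wC("nbrmech synthetic series", 80)
  wC("", 24)                      # aux_file
  wI(0, 2L); wI(1, 2L)            # qform_code, sform_code = scaled axes
  wF(c(0, 0, 0)); wF(c(0, 0, 0))  # quaternion, qoffset
  wF(c(voxelSize[1], 0, 0, 0))
  wF(c(0, voxelSize[2], 0, 0))
  wF(c(0, 0, voxelSize[3], 0))
  wC("", 16)                      # intent_name
  wC("n+1", 4)                    # magic
  writeBin(raw(4), con)           # no extensions
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by \code{\link{writeNifti}} (or any
#' uncompressed single-file little-endian NIfTI-1 with a common datatype)
#'
#' @param path .nii path
#' @return a \linkS4class{ScanSeries} (3D volumes become single-volume
#'   series)
#' @export
readNifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  rI <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = "little")
  rF <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  .check(rI(0, 4) == 348, "not a little-endian NIfTI-1 file")
  dim8 <- rI(40, 2, 8)
  nd <- dim8[1]
  .check(nd %in% c(3, 4), "only 3D/4D images are supported")
  d <- dim8[2:(1 + nd)]
  datatype <- rI(70, 2)
  pixdim <- rF(76, 8)
  voxOff <- rF(108)
  slope <- rF(112); inter <- rF(116)
  seek(con, voxOff)
  n <- prod(d)
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2,
                              endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4,
                              endian = "little")),
    "16" = readBin(con, "double", n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  if (slope != 0 && !(slope == 1 && inter == 0))
    dat <- dat * slope + inter
  if (nd == 3) d <- c(d, 1L)
  scanSeries(array(dat, d), voxelSize = pixdim[2:4],
             TR = if (pixdim[5] > 0) pixdim[5] else 2)
}
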