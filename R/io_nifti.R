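# Minimal NIfTI-1 reader/writer (.nii and .nii.gz), sufficient for CT
# volume + mask pairs: dims, datatype, bitpix, pixdim, vox_offset and
# scl_slope/scl_inter are honoured; orientation metadata is read but not
# applied (volumes are consumed slice-by-slice in stored axial order).
# No R NIfTI package ships with the supported environment, hence this
# deliberately small implementation.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `list(data, pixdim, datatype)` where `data` is an array with the
#'   stored dimensionality and `scl_slope`/`scl_inter` already applied.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  endian <- "little"
  if (hdr_size != 348L) {
    # 348 seen through the opposite byte order
    if (hdr_size != 1543569408L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  readBin(con, raw(), 36L)                                    # reserved
  dim <- readBin(con, integer(), 8L, size = 2L, endian = endian)
  readBin(con, double(), 3L, size = 4L, endian = endian)      # intent_p
  readBin(con, integer(), 1L, size = 2L, endian = endian)     # intent_code
  datatype <- readBin(con, integer(), 1L, size = 2L, endian = endian)
  readBin(con, integer(), 2L, size = 2L, endian = endian)     # bitpix, slice_start
  pixdim <- readBin(con, double(), 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, double(), 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, double(), 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, double(), 1L, size = 4L, endian = endian)
  readBin(con, raw(), 348L - 120L)                            # rest of header
  if (vox_offset > 348) readBin(con, raw(), as.integer(vox_offset) - 348L)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  nd <- dim[1]
  if (nd < 1L || nd > 7L) stop("corrupt NIfTI dim field")
  dims <- dim[2:(1 + nd)]
  n <- prod(dims)
  v <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
               endian = endian)
  if (length(v) < n) stop("truncated NIfTI data in ", path)
  v <- as.double(v)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    v <- v * scl_slope + scl_inter
  }
  list(data = array(v, dims), pixdim = pixdim[2:(1 + nd)],
       datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' @param data Numeric array (2D-7D).
#' @param path Destination `.nii` or `.nii.gz` path.
#' @param datatype `"float32"`, `"float64"`, `"int16"`, or `"uint8"`.
#' @param pixdim Voxel sizes, recycled to the array dimensionality.
#' @return The path, invisibly.
#' @export
write_nifti <- function(data, path, datatype = "float32", pixdim = 1) {
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype '", datatype, "'"))
  dt <- .nifti_dtypes[[as.character(code)]]
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  nd <- length(d)
  dimfield <- integer(8L)
  dimfield[1] <- nd
  dimfield[2:(1 + nd)] <- d
  if (nd < 7L) dimfield[(2 + nd):8] <- 1L
  pd <- numeric(8L)
  pd[2:(1 + nd)] <- rep_len(pixdim, nd)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L, endian = "little")
  writeBin(raw(36L), con)
  writeBin(as.integer(dimfield), con, size = 2L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")    # intent_p
  writeBin(0L, con, size = 2L, endian = "little")             # intent_code
  writeBin(code, con, size = 2L, endian = "little")
  writeBin(dt$bitpix, con, size = 2L, endian = "little")
  writeBin(0L, con, size = 2L, endian = "little")             # slice_start
  writeBin(pd, con, size = 4L, endian = "little")
  writeBin(352, con, size = 4L, endian = "little")            # vox_offset
  writeBin(1, con, size = 4L, endian = "little")              # scl_slope
  writeBin(0, con, size = 4L, endian = "little")              # scl_inter
  writeBin(raw(348L - 120L - 4L), con)                        # zero tail
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                      # extension flag
  v <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(v)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
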