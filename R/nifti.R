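#' Minimal NIfTI-1 input/output
#'
#' Single-file NIfTI-1 (`.nii`, or `.nii.gz` via a gz connection) with
#' float64 data, sform geometry, and up to 4 dimensions (the 4th axis is
#' used for displacement-field vector components). This covers the file
#' interchange needs of the pipeline; it is not a general NIfTI library.
#'
#' @param g an `image_grid`, or a plain 3D/4D array (then `spacing`/`origin`
#'   must be supplied).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param spacing,origin geometry when `g` is a bare array.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns an
#'   `image_grid` (3D) or a list with `data` (4D array), `spacing`, `origin`.
#' @export
write_nifti <- function(g, path, spacing = NULL, origin = NULL) {
  if (inherits(g, "image_grid")) {
    arr <- g$data; spacing <- g$spacing; origin <- g$origin
  } else {
    arr <- g
    if (is.null(spacing) || is.null(origin))
      stop("spacing and origin are required for bare arrays")
  }
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dimv <- rep(1L, 8); dimv[1] <- nd; dimv[2:(1 + nd)] <- dim(arr)
  pixdim <- rep(0, 8); pixdim[1] <- 1; pixdim[2:4] <- spacing
  writeBin(348L, con, size = 4)                        # sizeof_hdr
  writeBin(raw(36), con)                               # unused legacy fields
  writeBin(as.integer(dimv), con, size = 2)            # dim[8]
  writeBin(raw(14), con)                               # intent_p*, intent_code
  writeBin(c(64L, 64L), con, size = 2)                 # datatype FLOAT64, bitpix
  writeBin(0L, con, size = 2)                          # slice_start
  writeBin(pixdim, con, size = 4)                      # pixdim[8]
  writeBin(352, con, size = 4)                         # vox_offset
  writeBin(c(1, 0), con, size = 4)                     # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                          # slice_end
  writeBin(raw(2), con)                                # slice_code, xyzt_units
  writeBin(raw(16), con)                               # cal_max..toffset
  writeBin(raw(8), con)                                # glmax, glmin
  writeBin(raw(104), con)                              # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                   # qform=0, sform=1
  writeBin(rep(0, 6), con, size = 4)                   # quatern b,c,d + offsets
  writeBin(c(spacing[1], 0, 0, origin[1],
             0, spacing[2], 0, origin[2],
             0, 0, spacing[3], origin[3]), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)        # magic
  writeBin(raw(4), con)                                # extension flag
  writeBin(as.numeric(arr), con, size = 8)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  sz <- readBin(hdr[1:4], "integer", size = 4)
  if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  dimv <- readBin(hdr[41:56], "integer", n = 8, size = 2)
  datatype <- readBin(hdr[71:72], "integer", size = 2)
  pixdim <- readBin(hdr[77:108], "numeric", n = 8, size = 4)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4)
  srow <- readBin(hdr[281:328], "numeric", n = 12, size = 4)
  nd <- dimv[1]; dims <- dimv[2:(1 + nd)]
  n <- prod(dims)
  if (vox_offset > 352) readBin(con, "raw", n = vox_offset - 352)
  vals <- switch(as.character(datatype),
    "64" = readBin(con, "numeric", n = n, size = 8),
    "16" = readBin(con, "numeric", n = n, size = 4),
    "8"  = readBin(con, "integer", n = n, size = 4),
    "4"  = readBin(con, "integer", n = n, size = 2),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    stop("unsupported NIfTI datatype: ", datatype))
  arr <- array(as.numeric(vals), dims)
  spacing <- pixdim[2:4]
  origin <- c(srow[4], srow[8], srow[12])
  if (nd == 3L) image_grid(arr, spacing, origin)
  else list(data = arr, spacing = spacing, origin = origin)
}

#' Write a displacement field as 4D NIfTI (last axis = vector component)
#' @param dvf a `displacement_field`.
#' @param path output path.
#' @export
write_dvf_nifti <- function(dvf, path) {
  write_nifti(dvf$u, path, spacing = dvf$spacing, origin = dvf$origin)
}

#' @rdname write_dvf_nifti
#' @export
read_dvf_nifti <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$data)) != 4L || dim(x$data)[4] != 3L)
    stop("not a 3-component displacement field: ", path)
  displacement_field(x$data, x$spacing, x$origin)
}
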