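#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained single-file NIfTI-1 (`.nii` / `.nii.gz`) reader and writer
#' covering what the pipeline needs: 2D/3D volumes, voxel spacing from
#' `pixdim`, translation-only spatial offset, common scalar datatypes, both
#' byte orders, and the `scl_slope`/`scl_inter` intensity scaling. Rotated
#' affines, extensions and `.hdr`/`.img` pairs are out of scope; volumes
#' written by this package use float64 with an axis-aligned sform.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return [read_nifti()] returns a [voxel_grid()]; [write_nifti()] returns
#'   `path` invisibly.
#' @name nifti_io
NULL

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb") # transparently handles plain .nii too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_input("truncated NIfTI header in %s", path)
  rd <- function(what, n, size, off, endian, signed = TRUE)
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L) endian <- "big"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L)
    stop_input("%s is not a NIfTI-1 file (bad sizeof_hdr)", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_input("%s has unsupported NIfTI magic '%s'", path, magic)
  if (magic == "ni1")
    stop_input("two-file NIfTI (.hdr/.img) is not supported")

  dims <- rd("integer", 8L, 2L, 40L, endian)
  ndim <- dims[1]
  if (ndim < 2L || ndim > 3L)
    stop_input("only 2D/3D NIfTI volumes are supported (ndim = %d)", ndim)
  shape <- dims[2:(1 + ndim)]
  if (ndim == 2L) shape <- c(shape, 1L)
  datatype <- rd("integer", 1L, 2L, 70L, endian)
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_input("unsupported NIfTI datatype %d", datatype)
  pixdim <- rd("double", 8L, 4L, 76L, endian)
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0 | !is.finite(spacing)] <- 1
  vox_offset <- rd("double", 1L, 4L, 108L, endian)
  scl_slope <- rd("double", 1L, 4L, 112L, endian)
  scl_inter <- rd("double", 1L, 4L, 116L, endian)
  srow_x <- rd("double", 4L, 4L, 280L, endian)
  srow_y <- rd("double", 4L, 4L, 296L, endian)
  srow_z <- rd("double", 4L, 4L, 312L, endian)
  sform_code <- rd("integer", 1L, 2L, 254L, endian)
  origin <- if (sform_code > 0L) c(srow_x[4], srow_y[4], srow_z[4])
            else c(0, 0, 0)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                  signed = spec$signed)
  if (length(vals) < n) stop_input("truncated NIfTI data in %s", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel_grid(array(vals, dim = shape), spacing, origin)
}

#' @rdname nifti_io
#' @param grid a [voxel_grid()] (or plain array, spacing 1 mm assumed).
#' @export
write_nifti <- function(grid, path) {
  if (!inherits(grid, "voxel_grid")) grid <- voxel_grid(grid, c(1, 1, 1))
  shape <- dim(grid$values)
  hdr <- raw(348L)
  put <- function(hdr, x, what, size, off) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 348L, "integer", 4L, 0L)
  hdr <- put(hdr, c(3L, as.integer(shape), 1L, 1L, 1L, 1L),
             "integer", 2L, 40L)
  hdr <- put(hdr, 64L, "integer", 2L, 70L)  # float64
  hdr <- put(hdr, 64L, "integer", 2L, 72L)  # bitpix
  hdr <- put(hdr, c(1, grid$spacing_mm, 1, 1, 1, 1), "double", 4L, 76L)
  hdr <- put(hdr, 352, "double", 4L, 108L)  # vox_offset
  hdr <- put(hdr, 1, "double", 4L, 112L)    # scl_slope
  hdr <- put(hdr, 0, "double", 4L, 116L)    # scl_inter
  hdr <- put(hdr, c(2L, 10L), "integer", 1L, 123L) # xyzt_units: mm, sec
  hdr <- put(hdr, c(0L, 1L), "integer", 2L, 252L)  # qform 0, sform 1
  hdr <- put(hdr, c(grid$spacing_mm[1], 0, 0, grid$origin_mm[1]),
             "double", 4L, 280L)
  hdr <- put(hdr, c(0, grid$spacing_mm[2], 0, grid$origin_mm[2]),
             "double", 4L, 296L)
  hdr <- put(hdr, c(0, 0, grid$spacing_mm[3], grid$origin_mm[3]),
             "double", 4L, 312L)
  hdr[345:348] <- as.raw(c(0x6e, 0x2b, 0x31, 0x00)) # "n+1\0"

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # extension flag
  writeBin(as.double(grid$values), con, size = 8L, endian = "little")
  invisible(path)
}
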