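#' 3-D image volume
#'
#' Container for a 3-D scalar grid together with its voxel spacing and a
#' voxel-to-world affine. World coordinates are in millimetres and are
#' obtained as `affine %*% c(i, j, k, 1)` with **0-based** voxel indices
#' (the NIfTI convention). Optional frame timing metadata (seconds
#' post-injection) supports dynamic PET frames.
#'
#' @param data numeric 3-D array (each dimension >= 2).
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   the origin placed so the world origin sits at the grid centre.
#' @param frame_start,frame_end optional frame window in seconds.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         frame_start = NULL, frame_end = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("each array dimension must be >= 2", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (dim(data) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, affine = affine,
         frame_start = frame_start, frame_end = frame_end),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  if (!is.null(x$frame_start))
    cat("  frame ", x$frame_start, "-", x$frame_end, " s\n", sep = "")
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' World-space centre of a volume's bounding box
#'
#' Geometric centre of the grid in world coordinates, used as the default
#' rotation centre throughout the package.
#'
#' @param vol an [image_volume].
#' @return numeric length-3 world point (mm).
#' @export
volume_center <- function(vol) {
  stopifnot(is_image_volume(vol))
  drop(vol$affine %*% c((dim(vol$data) - 1) / 2, 1))[1:3]
}

# world -> voxel (0-based) matrix
world_to_voxel <- function(vol) solve(vol$affine)

## ---------------------------------------------------------------------------
## Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, no extensions).
## The pre-installed stack has no NIfTI package for R, and only the header
## fields this package uses are honoured: dim, datatype, pixdim, sform/qform,
## scl_slope/scl_inter, vox_offset.
## ---------------------------------------------------------------------------

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

#' Read a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 reader (`.nii` or `.nii.gz`). The sform is
#' preferred for the voxel-to-world affine, falling back to the qform and
#' finally to a diagonal `pixdim` affine. Data are returned with
#' `scl_slope`/`scl_inter` applied.
#'
#' @param path file path.
#' @return an [image_volume].
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  sizeof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "little")
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "big")
    if (sizeof != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
    endian <- "big"
  }
  gethdr <- function(off, what, n, size)
    readBin(hdr[(off + 1):348], what, n, size, signed = TRUE, endian = endian)
  dims <- gethdr(40, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3-D NIfTI volume", call. = FALSE)
  d3 <- dims[2:4]
  nvol <- if (ndim >= 4L) max(1L, dims[5]) else 1L
  datatype <- gethdr(70, "integer", 1L, 2L)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- gethdr(76, "double", 8L, 4L)
  vox_offset <- gethdr(108, "double", 1L, 4L)
  scl_slope <- gethdr(112, "double", 1L, 4L)
  scl_inter <- gethdr(116, "double", 1L, 4L)
  qform_code <- gethdr(252, "integer", 1L, 2L)
  sform_code <- gethdr(254, "integer", 1L, 2L)
  srow <- matrix(gethdr(280, "double", 12L, 4L), 3L, 4L, byrow = TRUE)
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- gethdr(256, "double", 6L, 4L)  # quatern_b,c,d, qoffset_x,y,z
    b <- q[1]; cc <- q[2]; dd <- q[3]
    a2 <- max(0, 1 - b^2 - cc^2 - dd^2)
    a <- sqrt(a2)
    R <- matrix(c(
      a^2 + b^2 - cc^2 - dd^2, 2 * (b * cc - a * dd), 2 * (b * dd + a * cc),
      2 * (b * cc + a * dd), a^2 + cc^2 - b^2 - dd^2, 2 * (cc * dd - a * b),
      2 * (b * dd - a * cc), 2 * (cc * dd + a * b), a^2 + dd^2 - b^2 - cc^2),
      3L, 3L, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    affine <- diag(4)
    affine[1:3, 1:3] <- R %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    affine[1:3, 4] <- q[4:6]
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  skip <- max(0, round(vox_offset) - 348L)
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d3) * nvol
  x <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(x) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  x <- as.double(x)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  if (nvol > 1L) x <- x[seq_len(prod(d3))]  # first volume only
  image_volume(array(x, d3), spacing = abs(pixdim[2:4]), affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image (`.nii`, gzipped when the path ends in
#' `.gz`) with float32 data and the volume's affine stored as the sform
#' (code 1).
#'
#' @param vol an [image_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  d <- dim(vol$data)
  buf <- raw(352L)
  put <- function(buf, off, x, what, size) {
    b <- writeBin(if (what == "integer") as.integer(x) else as.double(x),
                  raw(), size, endian = "little")
    buf[(off + 1):(off + length(b))] <- b
    buf
  }
  buf <- put(buf, 0, 348L, "integer", 4L)
  buf <- put(buf, 40, c(3L, d, 1L, 1L, 1L, 1L), "integer", 2L)
  buf <- put(buf, 70, 16L, "integer", 2L)    # datatype float32
  buf <- put(buf, 72, 32L, "integer", 2L)    # bitpix
  buf <- put(buf, 76, c(1, vol$spacing, 0, 0, 0, 0), "double", 4L)
  buf <- put(buf, 108, 352, "double", 4L)    # vox_offset
  buf <- put(buf, 112, c(1, 0), "double", 4L)
  buf <- put(buf, 252, 0L, "integer", 2L)    # qform_code
  buf <- put(buf, 254, 1L, "integer", 2L)    # sform_code
  buf <- put(buf, 280, as.double(t(vol$affine[1:3, , drop = FALSE])),
             "double", 4L)
  buf <- put(buf, 344, charToRaw("n+1"), "integer", 1L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(buf, con)
  writeBin(as.double(vol$data), con, 4L, endian = "little")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Transform serialization: 4 rows of 4 floats, plus a JSON sidecar with the
## rigid parameters and rotation centre when available.
## ---------------------------------------------------------------------------

#' Write a transform to disk
#'
#' The 4x4 matrix is written as four whitespace-separated rows of four
#' numbers; when `params`/`center` are given, a `<path>.json` sidecar records
#' them.
#'
#' @param m 4x4 affine matrix.
#' @param path output path for the matrix text file.
#' @param params optional [rigid_params].
#' @param center optional rotation centre (world mm).
#' @return `path`, invisibly.
#' @export
write_transform <- function(m, path, params = NULL, center = NULL) {
  stopifnot(all(dim(m) == c(4L, 4L)))
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), path)
  if (!is.null(params) || !is.null(center)) {
    side <- list()
    if (!is.null(params)) side$params <- as.list(unclass(params))
    if (!is.null(center)) side$center <- as.numeric(center)
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a transform matrix written by [write_transform()]
#' @param path matrix text file.
#' @return 4x4 matrix.
#' @export
read_transform <- function(path) {
  x <- scan(path, quiet = TRUE)
  if (length(x) != 16L) stop("expected 16 numbers in ", path, call. = FALSE)
  matrix(x, 4L, 4L, byrow = TRUE)
}
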