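#' Rigid-body transform parameters
#'
#' The six decision variables of the registration: translations in mm and
#' rotations in degrees about the world x, y and z axes (right-handed,
#' counterclockwise positive looking down the axis toward the origin).
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations, degrees.
#' @return an object of class `rigid_params` (named numeric of length 6).
#' @export
rigid_params <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  p <- vapply(p, as.numeric, numeric(1))
  if (!all(is.finite(p)))
    stop("rigid parameters must all be finite", call. = FALSE)
  structure(p, class = "rigid_params")
}

as_rigid_params <- function(x) {
  if (inherits(x, "rigid_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("expected 6 rigid parameters", call. = FALSE)
  rigid_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' @export
print.rigid_params <- function(x, ...) {
  cat(sprintf("t = (%.4g, %.4g, %.4g) mm,  r = (%.4g, %.4g, %.4g) deg\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Build a rigid transform matrix
#'
#' Composes the 4x4 world-space matrix `T(tx,ty,tz) Rz Ry Rx` about a given
#' rotation centre: a world point is translated so the centre sits at the
#' origin, rotated about x, then y, then z, translated back, and finally
#' shifted by `(tx, ty, tz)`.
#'
#' @param params a [rigid_params] (or numeric length 6: tx,ty,tz,rx,ry,rz).
#' @param center rotation centre, world mm (length 3).
#' @return 4x4 rigid affine matrix (class `matrix`).
#' @export
build_transform <- function(params, center = c(0, 0, 0)) {
  p <- as_rigid_params(params)
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("`center` must be 3 finite world coordinates", call. = FALSE)
  ang <- p[4:6] * pi / 180
  R <- rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- p[1:3] + center - R %*% center
  m
}

is_rigid_matrix <- function(m, tol = 1e-6) {
  all(dim(m) == c(4L, 4L)) &&
    all(abs(m[4, ] - c(0, 0, 0, 1)) < tol) &&
    all(abs(crossprod(m[1:3, 1:3]) - diag(3)) < tol) &&
    abs(det(m[1:3, 1:3]) - 1) < tol
}

#' Decompose a rigid matrix into parameters
#'
#' Inverts [build_transform()]: extracts Euler angles from the `Rz Ry Rx`
#' factorization (ry constrained to (-90, 90) degrees) and the translation
#' relative to the given rotation centre, such that
#' `build_transform(result, center)` reproduces `m`.
#'
#' @param m 4x4 rigid matrix (orthonormal rotation block, det +1).
#' @param center rotation centre used when the matrix was built, world mm.
#' @return a [rigid_params].
#' @export
decompose_transform <- function(m, center = c(0, 0, 0)) {
  if (!is_rigid_matrix(m))
    stop("`m` is not a rigid transform (orthonormal, det +1, bottom row 0 0 0 1)",
         call. = FALSE)
  center <- as.numeric(center)
  R <- m[1:3, 1:3]
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(abs(ry) * 180 / pi - 90) < 1e-6)
    stop("degenerate decomposition: |ry| at 90 degrees (gimbal lock)",
         call. = FALSE)
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  t <- m[1:3, 4] - center + R %*% center
  rigid_params(t[1], t[2], t[3],
               rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' Resample a volume under a rigid transform
#'
#' Pull-back resampling on the volume's own grid: the output value at voxel
#' `v` is the input sampled at world position `solve(m) %*% world(v)`, so the
#' image content is *moved by* `m`. Out-of-field samples are 0. Use
#' `"nearest"` for label/mask volumes and `"trilinear"` for intensities.
#'
#' @param vol an [image_volume].
#' @param m 4x4 rigid matrix (world space).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return an [image_volume] on the same grid.
#' @export
resample_volume <- function(vol, m, interpolation = c("trilinear", "nearest")) {
  stopifnot(is_image_volume(vol))
  interpolation <- match.arg(interpolation)
  if (!is_rigid_matrix(m))
    stop("`m` is not a rigid transform", call. = FALSE)
  # output voxel -> input voxel, through world space
  A <- solve(vol$affine) %*% solve(m) %*% vol$affine
  out <- .resample_cpp(as.double(vol$data), dim(vol$data),
                       A[1:3, , drop = FALSE],
                       if (interpolation == "trilinear") 0L else 1L)
  image_volume(array(out, dim(vol$data)), spacing = vol$spacing,
               affine = vol$affine, frame_start = vol$frame_start,
               frame_end = vol$frame_end)
}
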