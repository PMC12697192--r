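#' Rigid transforms in 3D
#'
#' A rigid transform maps points by `p -> R p + t` with `R` a proper rotation
#' (orthonormal, det +1) and `t` a translation in millimetres. All scene,
#' marker and implant geometry in the package lives in lab-frame millimetres,
#' right-handed.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(round(x$translation, 6)), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param points n x 3 matrix of coordinates (rows are points).
#' @return Transformed n x 3 matrix; rownames (labels) preserved.
#' @export
transform_points <- function(tf, points) {
  points <- as_pointset(points)
  out <- points %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  dimnames(out) <- dimnames(points)
  out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform "apply `b`, then `a`".
#' @param a,b `rigid_transform`s.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

identity_transform <- function() rigid_transform()

#' Rotation matrix from Cardan angles
#'
#' Angles are applied about the fixed x, then y, then z axes, i.e.
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` acting on column vectors. Degrees.
#'
#' @param rx,ry,rz rotations in degrees about the x, y and z axes.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_cardan <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Cardan angles from a rotation matrix
#'
#' Inverse of [rotation_from_cardan()] (x-y-z order); returns degrees.
#' Valid away from the gimbal-lock singularity at ry = +/-90 deg, far beyond
#' the sub-2-degree rotations migration analysis deals in.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric `c(rx, ry, rz)` in degrees.
#' @export
cardan_from_rotation <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

#' Random rigid transform
#'
#' Rotation axis uniform on the sphere, angle uniform in
#' `[0, max_angle_deg]`, translation uniform in a cube of half-width
#' `max_trans_mm`. Used for patient repositioning between examinations.
#'
#' @param max_angle_deg,max_trans_mm bounds on rotation (deg) and
#'   translation (mm).
#' @export
random_rigid_transform <- function(max_angle_deg = 15, max_trans_mm = 50) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(R, stats::runif(3, -max_trans_mm, max_trans_mm))
}

# coerce to labelled n x 3 point matrix
as_pointset <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("point sets must have 3 columns (x, y, z)")
  if (any(!is.finite(x))) stop("non-finite coordinates in point set")
  x
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Row-major rotation, translation in mm.
#' @param tf `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(tf$rotation)), translation = tf$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
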