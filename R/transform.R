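#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1 (within 1e-9)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param points `n x 3` matrix or length-3 vector.
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(is_rigid_transform(transform))
  if (is.null(dim(points))) {
    return(as.numeric(transform$rotation %*% points + transform$translation))
  }
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` applies `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return Their composition as a [rigid_transform()].
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform.
#' @export
transform_inverse <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about `axis` (right-hand rule).
#' @param axis Length-3 vector (need not be unit).
#' @param angle_deg Angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Geodesic angle (radians) of a rotation matrix.
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}
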