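#' Principal longitudinal axis of an elongated bone
#'
#' The dominant principal axis of the vertex cloud (eigenvector of the largest
#' eigenvalue of the vertex covariance). Long bones such as the radius, ulna
#' and capitate are strongly elongated, so this axis is a stable estimate of
#' the anatomical long axis. The direction is oriented distally when an
#' anatomical frame is supplied (positive projection onto `e_lon`), otherwise
#' the sign is fixed deterministically (largest-magnitude component positive).
#'
#' @param mesh A [triangle_mesh()].
#' @param frame Optional [anatomical_frame()] used to orient the direction
#'   distally.
#' @param min_elongation Minimum ratio of largest to second-largest principal
#'   standard deviation; below this the mesh is considered near-isotropic and
#'   an error is raised.
#' @return A list with `point` (the vertex centroid) and `direction` (unit
#'   vector).
#' @export
principal_longitudinal_axis <- function(mesh, frame = NULL,
                                        min_elongation = 1.5) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  ctr <- colMeans(v)
  cv <- crossprod(sweep(v, 2, ctr)) / nrow(v)
  eg <- eigen(cv, symmetric = TRUE)
  sd1 <- sqrt(eg$values[1])
  sd2 <- sqrt(max(eg$values[2], 0))
  if (!is.finite(sd1) || sd2 <= 0 || sd1 / sd2 < min_elongation) {
    stop(sprintf(
      "mesh is not elongated enough for a principal axis (ratio %.2f < %.2f)",
      sd1 / max(sd2, .Machine$double.eps), min_elongation))
  }
  dir <- eg$vectors[, 1]
  if (!is.null(frame)) {
    if (sum(dir * frame$e_lon) < 0) dir <- -dir
  } else {
    k <- which.max(abs(dir))
    if (dir[k] < 0) dir <- -dir
  }
  list(point = ctr, direction = dir / sqrt(sum(dir^2)))
}
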