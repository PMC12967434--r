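#' Anatomical coordinate frame of the wrist
#'
#' Orthonormal, right-handed local coordinate system used by all measurements:
#' `e_ru` points from radial to ulnar, `e_pd` from palmar to dorsal, and
#' `e_lon` from proximal to distal. All quantities are expressed in this frame
#' of the radius: the sagittal plane is spanned by (`e_pd`, `e_lon`), the
#' coronal plane by (`e_ru`, `e_lon`) and the axial plane by (`e_ru`, `e_pd`).
#'
#' Left wrists are mirrored into the right-hand convention before measurement
#' (see [frame_normalize_side()]), so the dorsal-positive sign conventions are
#' uniform across sides.
#'
#' @param origin Length-3 point (mm).
#' @param e_ru,e_pd,e_lon Length-3 unit vectors; must be mutually orthonormal
#'   within 1e-9 and form a right-handed triple (after side normalization).
#' @param side `"left"` or `"right"`.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, e_ru, e_pd, e_lon, side = "right") {
  origin <- as.numeric(origin); e_ru <- as.numeric(e_ru)
  e_pd <- as.numeric(e_pd); e_lon <- as.numeric(e_lon)
  stopifnot(length(origin) == 3, length(e_ru) == 3, length(e_pd) == 3,
            length(e_lon) == 3, side %in% c("left", "right"))
  B <- cbind(e_ru, e_pd, e_lon)
  if (max(abs(crossprod(B) - diag(3))) > 1e-9) {
    stop("frame axes must be mutually orthonormal within 1e-9")
  }
  if (det(B) < 0) {
    stop("frame axes must form a right-handed triple; ",
         "mirror left-side data with frame_normalize_side() first")
  }
  structure(list(origin = origin, e_ru = e_ru, e_pd = e_pd, e_lon = e_lon,
                 side = side),
            class = "anatomical_frame")
}

is_anatomical_frame <- function(x) inherits(x, "anatomical_frame")

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> side=%s origin=(%.2f, %.2f, %.2f) mm\n",
              x$side, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Transform an anatomical frame rigidly
#' @param frame An [anatomical_frame()].
#' @param transform A [rigid_transform()].
#' @return The moved frame.
#' @export
frame_transform <- function(frame, transform) {
  R <- transform$rotation
  anatomical_frame(
    transform_points(transform, frame$origin),
    as.numeric(R %*% frame$e_ru),
    as.numeric(R %*% frame$e_pd),
    as.numeric(R %*% frame$e_lon),
    frame$side
  )
}

#' Normalize a left wrist into the right-hand convention
#'
#' Mirrors meshes and frame across the sagittal plane (the plane normal to
#' `e_ru` through the frame origin), flips `e_ru`, and relabels the side as
#' right. Right-side inputs are returned unchanged. All sign conventions
#' downstream (dorsal positive, ulnar positive) then hold for both sides.
#'
#' @param frame An [anatomical_frame()].
#' @param meshes Optional named list of [triangle_mesh()] objects to mirror
#'   together with the frame.
#' @return A list with `frame` and `meshes`.
#' @export
frame_normalize_side <- function(frame, meshes = list()) {
  stopifnot(is_anatomical_frame(frame))
  if (frame$side == "right") {
    return(list(frame = frame, meshes = meshes))
  }
  n <- frame$e_ru
  o <- frame$origin
  mirror_pts <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    d <- (sweep(p, 2, o) %*% n)[, 1]
    p - 2 * d %o% n
  }
  new_frame <- anatomical_frame(o, -n, frame$e_pd, frame$e_lon, "right")
  new_meshes <- lapply(meshes, function(m) {
    v <- mirror_pts(m$vertices)
    triangle_mesh(v, m$faces[, c(1, 3, 2), drop = FALSE], m$bone_label)
  })
  list(frame = new_frame, meshes = new_meshes)
}

#' Build an anatomical frame from explicit axis hints
#'
#' Surrogate for automatic local coordinate systems derived from anatomy:
#' takes a longitudinal direction and an approximate palmar-dorsal direction,
#' re-orthogonalizes (Gram-Schmidt), and completes the right-handed triple.
#'
#' @param origin Length-3 point (mm).
#' @param lon Approximate proximal-to-distal direction.
#' @param pd Approximate palmar-to-dorsal direction (projected orthogonal to
#'   `lon`).
#' @param side `"left"` or `"right"`.
#' @return An [anatomical_frame()]. For left wrists the returned frame is
#'   still labelled left; run [frame_normalize_side()] before measuring.
#' @export
frame_from_axes <- function(origin, lon, pd, side = "right") {
  e_lon <- lon / sqrt(sum(lon^2))
  pd_o <- pd - sum(pd * e_lon) * e_lon
  if (sqrt(sum(pd_o^2)) < 1e-8) stop("pd direction parallel to lon")
  e_pd <- pd_o / sqrt(sum(pd_o^2))
  e_ru <- c(
    e_pd[2] * e_lon[3] - e_pd[3] * e_lon[2],
    e_pd[3] * e_lon[1] - e_pd[1] * e_lon[3],
    e_pd[1] * e_lon[2] - e_pd[2] * e_lon[1]
  )
  if (side == "left") {
    # left wrists carry a left-handed anatomical triple until normalized
    structure(list(origin = as.numeric(origin), e_ru = -e_ru, e_pd = e_pd,
                   e_lon = e_lon, side = "left"),
              class = "anatomical_frame")
  } else {
    anatomical_frame(origin, e_ru, e_pd, e_lon, side)
  }
}
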