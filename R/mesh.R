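#' Triangle surface mesh of a single wrist bone
#'
#' Container for a closed triangle surface in millimetre coordinates, the unit
#' every downstream measurement assumes. Vertices are stored as an `n x 3`
#' numeric matrix and faces as an `m x 3` integer matrix of 1-based vertex
#' indices.
#'
#' @param vertices Numeric matrix (`n x 3`), one vertex per row, in mm.
#' @param faces Integer matrix (`m x 3`), counter-clockwise vertex index
#'   triples (1-based) as seen from outside the bone, so face normals point
#'   outward.
#' @param bone_label Character scalar, one of `"radius"`, `"ulna"`,
#'   `"lunate"`, `"triquetrum"`, `"capitate"` or `NA` for anonymous meshes.
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `bone_label`.
#' @export
triangle_mesh <- function(vertices, faces, bone_label = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(vertices) < 4L) stop("a triangle mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  known <- c("radius", "ulna", "lunate", "triquetrum", "capitate")
  if (!is.na(bone_label) && !bone_label %in% known) {
    stop("bone_label must be one of: ", paste(known, collapse = ", "))
  }
  structure(
    list(vertices = vertices, faces = faces, bone_label = bone_label),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %s: %d vertices, %d faces\n",
    if (is.na(x$bone_label)) "(unlabelled)" else x$bone_label,
    nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Check mesh validity and watertightness
#'
#' Reports whether every edge is shared by exactly two faces (watertight,
#' manifold) and lists open (boundary) edges. Segmented bone surfaces are
#' intended to be watertight; boundary edges typically indicate a cropped
#' field of view.
#'
#' @param mesh A [triangle_mesh()].
#' @return A list with `watertight` (logical), `n_boundary_edges`,
#'   `boundary_edges` (matrix of vertex index pairs) and `boundary_vertices`
#'   (integer vector).
#' @export
mesh_validate <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_keys <- names(cnt)[cnt != 2L]
  if (length(open_keys)) {
    parts <- do.call(rbind, strsplit(open_keys, " ", fixed = TRUE))
    be <- matrix(as.integer(parts), ncol = 2)
  } else {
    be <- matrix(integer(0), ncol = 2)
  }
  list(
    watertight = nrow(be) == 0L,
    n_boundary_edges = nrow(be),
    boundary_edges = be,
    boundary_vertices = sort(unique(as.integer(be)))
  )
}

#' Boundary vertices of a mesh
#'
#' Vertices lying on an edge that belongs to fewer than two faces. These are
#' excluded from curvature estimation.
#' @param mesh A [triangle_mesh()].
#' @return Integer vector of vertex indices (possibly empty).
#' @export
mesh_boundary_vertices <- function(mesh) {
  mesh_validate(mesh)$boundary_vertices
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param transform A [rigid_transform()].
#' @return The transformed mesh (same faces, moved vertices).
#' @export
mesh_transform <- function(mesh, transform) {
  stopifnot(is_triangle_mesh(mesh))
  v <- transform_points(transform, mesh$vertices)
  triangle_mesh(v, mesh$faces, mesh$bone_label)
}

#' Mirror a mesh across a plane through the origin
#'
#' Used for left-to-right side normalization: left wrists are mirrored across
#' the sagittal plane so a single right-hand sign convention applies. Face
#' windings are flipped so normals keep pointing outward.
#'
#' @param mesh A [triangle_mesh()].
#' @param normal Unit normal of the mirror plane (default the x axis,
#'   i.e. the radioulnar direction).
#' @return The mirrored mesh.
#' @export
mesh_mirror <- function(mesh, normal = c(1, 0, 0)) {
  stopifnot(is_triangle_mesh(mesh))
  n <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices - 2 * (mesh$vertices %*% n)[, 1] %o% n
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$bone_label)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  n
}

# Area-weighted outward vertex normals.
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) # length = 2*area, already area weighted
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(n))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(n))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Sum `values` into `n` bins given by `index` (1-based). Vectorized accumulate.
tapply_add <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
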