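#' Named anatomical landmarks of the distal radius and ulna
#'
#' Bundle of the named 3-D points (world coordinates, mm) used by the four
#' ulnar-sided parameters:
#' \describe{
#'   \item{distal_ulnar_point}{most distal point of the ulnar head articular
#'     surface after styloid removal (3-D ulnar variance).}
#'   \item{sigmoid_distal_point}{most distal point of the sigmoid notch
#'     (the "radial point" of the 3-D ulnar variance).}
#'   \item{palmar_margin, dorsal_margin}{palmar and dorsal margins of the
#'     sigmoid notch; their chord defines the notch width.}
#'   \item{notch_midpoint}{midpoint of the two margins (exactly).}
#'   \item{palmar_radial_corner}{palmar-radial corner of the distal radius
#'     rim (start of the palmar-radial line).}
#'   \item{ulnar_epicentre}{intersection of the ulna's longitudinal axis with
#'     the distal cortex.}
#'   \item{ulnar_styloid_tip}{tip of the ulnar styloid process.}
#'   \item{ulnar_head_palmar_point}{most palmar point of the ulnar head.}
#' }
#'
#' @param points Named list of length-3 numeric points; all names above must
#'   be present.
#' @param source `"auto"` (detected) or `"provided"` (externally supplied,
#'   e.g. from a statistical-shape-model pipeline).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, source = c("auto", "provided")) {
  source <- match.arg(source)
  required <- c(
    "distal_ulnar_point", "sigmoid_distal_point", "palmar_margin",
    "dorsal_margin", "notch_midpoint", "palmar_radial_corner",
    "ulnar_epicentre", "ulnar_styloid_tip", "ulnar_head_palmar_point"
  )
  missing <- setdiff(required, names(points))
  if (length(missing)) {
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  }
  points <- lapply(points[required], function(p) {
    p <- as.numeric(p)
    stopifnot(length(p) == 3, all(is.finite(p)))
    p
  })
  mid_gap <- sqrt(sum((points$notch_midpoint -
                         (points$palmar_margin + points$dorsal_margin) / 2)^2))
  if (mid_gap > 1e-9) {
    stop("notch_midpoint must be the midpoint of the sigmoid notch margins")
  }
  if (sqrt(sum((points$palmar_margin - points$dorsal_margin)^2)) <= 0) {
    stop("sigmoid notch width must be positive")
  }
  structure(list(points = points, source = source), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> (%s)\n", x$source))
  for (nm in names(x$points)) {
    cat(sprintf("  %-24s (%8.3f, %8.3f, %8.3f) mm\n", nm,
                x$points[[nm]][1], x$points[[nm]][2], x$points[[nm]][3]))
  }
  invisible(x)
}

is_landmark_set <- function(x) inherits(x, "landmark_set")

#' Transform all landmarks rigidly
#' @param landmarks A [landmark_set()].
#' @param transform A [rigid_transform()].
#' @return The moved landmark set.
#' @export
landmarks_transform <- function(landmarks, transform) {
  landmark_set(lapply(landmarks$points, function(p) {
    transform_points(transform, p)
  }), source = landmarks$source)
}

#' Read or write landmarks as JSON
#'
#' Round-trips exactly: coordinates are serialized at full double precision.
#' The file is a JSON array of `{bone, name, xyz_mm}` records.
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @return `landmarks_write()` returns `path` invisibly; `landmarks_read()`
#'   returns a [landmark_set()] with `source = "provided"`.
#' @export
landmarks_write <- function(landmarks, path) {
  bones <- c(
    distal_ulnar_point = "ulna", sigmoid_distal_point = "radius",
    palmar_margin = "radius", dorsal_margin = "radius",
    notch_midpoint = "radius", palmar_radial_corner = "radius",
    ulnar_epicentre = "ulna", ulnar_styloid_tip = "ulna",
    ulnar_head_palmar_point = "ulna"
  )
  recs <- lapply(names(landmarks$points), function(nm) {
    list(bone = bones[[nm]], name = nm, xyz_mm = landmarks$points[[nm]])
  })
  jsonlite::write_json(recs, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname landmarks_write
#' @export
landmarks_read <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- stats::setNames(
    lapply(recs, function(r) as.numeric(unlist(r$xyz_mm))),
    vapply(recs, function(r) r$name, character(1))
  )
  landmark_set(pts, source = "provided")
}

#' Tip of the ulnar styloid process
#'
#' The most distal ulna vertex (maximum projection on the frame's `e_lon`);
#' the styloid process is the most distal part of the ulna. Ties are broken
#' deterministically by lowest vertex index, with a warning.
#'
#' @param ulna Ulna [triangle_mesh()].
#' @param frame The radius [anatomical_frame()] (the common measurement
#'   frame).
#' @return Length-3 point (mm).
#' @export
ulnar_styloid_tip <- function(ulna, frame) {
  proj <- (ulna$vertices %*% frame$e_lon)[, 1]
  pick_max(ulna$vertices, proj, "ulnar styloid tip")
}

#' Most distal point of the ulnar head articular surface
#'
#' Removes the styloid process — all vertices inside a cylinder of radius
#' `styloid_cylinder_radius` whose axis runs through the styloid tip parallel
#' to `e_lon` — and returns the most distal remaining vertex.
#'
#' @param ulna Ulna [triangle_mesh()].
#' @param frame The radius [anatomical_frame()].
#' @param styloid_cylinder_radius Cylinder radius in mm (default 4, a typical
#'   styloid base width).
#' @return Length-3 point (mm).
#' @export
distal_ulnar_articular_point <- function(ulna, frame,
                                         styloid_cylinder_radius = 4) {
  v <- ulna$vertices
  lon <- (v %*% frame$e_lon)[, 1]
  tip <- v[which.max(lon), ]
  # perpendicular (axial-plane) distance from the styloid axis
  d <- sweep(v, 2, tip)
  d_perp2 <- rowSums(d^2) - (d %*% frame$e_lon)[, 1]^2
  # strictly inside the cylinder is removed; radius 0 removes nothing
  keep <- d_perp2 >= styloid_cylinder_radius^2
  if (!any(keep)) {
    stop("styloid cylinder removed the entire distal ulna; ",
         "reduce styloid_cylinder_radius")
  }
  pick_max(v[keep, , drop = FALSE], lon[keep], "distal ulnar point")
}

#' Sigmoid notch detection by curvature classification
#'
#' Classifies radius vertices with surface curvature exceeding
#' `curvature_threshold` (default 0.1 / mm; concave positive) as sigmoid
#' notch, restricted to a search window on the ulnar-facing distal radius
#' (distal 25% of the longitudinal extent, ulnar half of the radioulnar
#' extent). Returns the largest face-connected component and its most distal
#' vertex (the "radial point" of 3-D ulnar variance).
#'
#' @param radius Radius [triangle_mesh()].
#' @param frame The radius [anatomical_frame()].
#' @param curvature_threshold Classification threshold in 1/mm.
#' @param distal_fraction,ulnar_fraction Search-window fractions of the
#'   longitudinal / radioulnar extents.
#' @param curvature_mode Passed to [mean_curvature()].
#' @return A list with `region` (integer vertex indices) and
#'   `sigmoid_distal_point` (length-3 point).
#' @export
sigmoid_notch_region <- function(radius, frame, curvature_threshold = 0.1,
                                 distal_fraction = 0.25, ulnar_fraction = 0.5,
                                 curvature_mode = "longitudinal") {
  v <- radius$vertices
  lon <- (v %*% frame$e_lon)[, 1]
  ru <- (v %*% frame$e_ru)[, 1]
  h <- mean_curvature(radius, mode = curvature_mode,
                      direction = frame$e_lon)
  in_window <- lon >= max(lon) - distal_fraction * diff(range(lon)) &
    ru >= max(ru) - ulnar_fraction * diff(range(ru))
  sel <- which(in_window & !is.na(h) & h > curvature_threshold)
  if (!length(sel)) {
    stop("no vertices exceed the curvature threshold inside the search ",
         "window; consider lowering curvature_threshold")
  }
  comp <- largest_component(radius$faces, sel)
  # morphological opening: the discrete classification boundary is jagged
  # and can carry single-vertex spurs; eroding one ring and dilating back
  # within the component removes them while restoring the true boundary
  opened <- vertex_opening(radius$faces, comp)
  if (length(opened)) comp <- opened
  # most distal region vertex; among longitudinal ties take the vertex
  # nearest the notch's palmar-dorsal midline
  pd <- (v %*% frame$e_pd)[, 1]
  point <- pick_max2(v[comp, , drop = FALSE], lon[comp],
                     -abs(pd[comp] - mean(pd[comp])))
  list(region = comp, sigmoid_distal_point = point)
}

#' Sigmoid notch margins and the palmar-radial corner
#'
#' Geometric surrogate for statistical-shape-model landmarking of the distal
#' radius: the palmar and dorsal margins are the extreme notch-region
#' vertices along `e_pd`; the palmar-radial corner is the most palmar vertex
#' of the distal radius rim radial to the notch; the notch midpoint is the
#' exact mean of the margins.
#'
#' @param radius Radius [triangle_mesh()].
#' @param frame The radius [anatomical_frame()].
#' @param notch_region Integer vertex indices from [sigmoid_notch_region()].
#' @param rim_tolerance Vertices within this distance (mm) of the most distal
#'   radius vertex count as the distal rim.
#' @return List with `palmar_margin`, `dorsal_margin`, `palmar_radial_corner`
#'   and `notch_midpoint` points.
#' @export
sigmoid_notch_margins <- function(radius, frame, notch_region,
                                  rim_tolerance = 1.5) {
  v <- radius$vertices
  pd <- (v %*% frame$e_pd)[, 1]
  lon <- (v %*% frame$e_lon)[, 1]
  ru <- (v %*% frame$e_ru)[, 1]
  reg <- notch_region
  if (!length(reg)) stop("empty notch region")
  # margins: extreme along e_pd; among ties, the deepest (most radial)
  # vertex of that rim column, i.e. the floor of the facet's widest chord
  palmar <- pick_max2(v[reg, , drop = FALSE], -pd[reg], -ru[reg])
  dorsal <- pick_max2(v[reg, , drop = FALSE], pd[reg], -ru[reg])
  rim <- which(lon >= max(lon) - rim_tolerance & ru < min(ru[reg]))
  if (!length(rim)) stop("no distal rim vertices radial to the notch")
  # corner: most palmar, then most distal among palmar ties
  corner <- pick_max2(v[rim, , drop = FALSE], -pd[rim], lon[rim])
  list(
    palmar_margin = palmar, dorsal_margin = dorsal,
    palmar_radial_corner = corner, notch_midpoint = (palmar + dorsal) / 2
  )
}

#' Ulnar epicentre
#'
#' Intersection of the ulna's longitudinal axis (principal axis of the
#' vertex cloud, oriented distally) with the distal cortex: the ray is cast
#' distally and the farthest surface intersection along `e_lon` is returned.
#'
#' @param ulna Ulna [triangle_mesh()].
#' @param frame The radius [anatomical_frame()].
#' @return Length-3 point (mm).
#' @export
ulnar_epicentre <- function(ulna, frame) {
  ax <- principal_longitudinal_axis(ulna, frame)
  hits <- line_mesh_intersections(ulna, ax$point, ax$direction)
  if (!nrow(hits)) {
    stop("ulnar longitudinal axis does not intersect the ulna surface")
  }
  lon <- (hits %*% frame$e_lon)[, 1]
  hits[which.max(lon), ]
}

#' Most palmar point of the ulnar head
#'
#' Restricted to the distal head window (distal `head_fraction` of the
#' ulna's longitudinal extent, styloid cylinder excluded). The extremal
#' vertex (minimum projection on `e_pd`; ties break to the lowest index) is
#' refined to a sub-vertex surface extremum by a local quadratic fit over
#' its one-ring, so the landmark varies smoothly as the palmar direction
#' rotates during forearm motion instead of jumping between mesh vertices.
#' This landmark is re-evaluated per frame (it is an extremum in the
#' instantaneous radius frame, like the proximity sites), never
#' transported.
#'
#' @param ulna Ulna [triangle_mesh()].
#' @param frame The radius [anatomical_frame()].
#' @param head_fraction Fraction of the longitudinal extent forming the head
#'   window (default 0.15).
#' @param styloid_cylinder_radius As in [distal_ulnar_articular_point()].
#' @return Length-3 point (mm).
#' @export
ulnar_head_palmar_point <- function(ulna, frame, head_fraction = 0.15,
                                    styloid_cylinder_radius = 4) {
  v <- ulna$vertices
  lon <- (v %*% frame$e_lon)[, 1]
  pd <- (v %*% frame$e_pd)[, 1]
  tip <- v[which.max(lon), ]
  d <- sweep(v, 2, tip)
  d_perp2 <- rowSums(d^2) - (d %*% frame$e_lon)[, 1]^2
  win <- lon >= max(lon) - head_fraction * diff(range(lon)) &
    d_perp2 >= styloid_cylinder_radius^2
  if (!any(win)) stop("empty ulnar head window")
  ids <- which(win)
  best <- ids[which(-pd[ids] >= max(-pd[ids]) - 1e-12)[1]]
  refine_extremum(ulna, best, -frame$e_pd)
}

# Sub-vertex extremum of the surface height along `dir` near vertex `id`:
# weighted quadratic fit of the one-ring in local tangent coordinates.
refine_extremum <- function(mesh, id, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  ring <- setdiff(unique(as.integer(f[rowSums(f == id) > 0L, ])), id)
  if (length(ring) < 5L) return(v[id, ])
  pts <- v[c(id, ring), , drop = FALSE]
  q <- sweep(pts, 2, v[id, ])
  eg <- eigen(crossprod(q), symmetric = TRUE)
  t1 <- eg$vectors[, 1]; t2 <- eg$vectors[, 2]; nrm <- eg$vectors[, 3]
  u <- q %*% t1; w <- q %*% t2
  X <- cbind(1, u, w, u^2, u * w, w^2)
  fit <- function(y) tryCatch(qr.solve(X, y), error = function(e) NULL)
  ch <- fit(q %*% dir)
  cn <- fit(q %*% nrm)
  if (is.null(ch) || is.null(cn)) return(v[id, ])
  H <- matrix(c(2 * ch[4], ch[5], ch[5], 2 * ch[6]), 2, 2)
  g <- c(ch[2], ch[3])
  sol <- tryCatch(solve(H, -g), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) return(v[id, ])
  rad <- sqrt(max(u^2 + w^2))
  if (sqrt(sum(sol^2)) > rad) return(v[id, ]) # extremum outside the ring
  hn <- sum(cn * c(1, sol[1], sol[2], sol[1]^2, sol[1] * sol[2], sol[2]^2))
  v[id, ] + sol[1] * t1 + sol[2] * t2 + hn * nrm
}

#' Detect the full landmark set automatically
#'
#' Runs all landmark detectors on the static radius and ulna meshes in the
#' common radius frame. Detection is deterministic: identical inputs give
#' identical landmarks. Externally supplied landmarks (e.g. from a
#' statistical-shape-model pipeline) can be passed through `provided` and
#' bypass detection entirely.
#'
#' @param radius,ulna [triangle_mesh()] objects in world coordinates.
#' @param frame The radius [anatomical_frame()].
#' @param config Optional list overriding detector settings:
#'   `curvature_threshold`, `styloid_cylinder_radius`, `head_fraction`,
#'   `distal_fraction`, `ulnar_fraction`, `curvature_mode`.
#' @param provided Optional [landmark_set()] (or path to a landmark JSON)
#'   returned as-is.
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(radius, ulna, frame, config = list(),
                             provided = NULL) {
  if (!is.null(provided)) {
    if (is.character(provided)) provided <- landmarks_read(provided)
    stopifnot(is_landmark_set(provided))
    return(provided)
  }
  cfg <- utils::modifyList(list(
    curvature_threshold = 0.1, styloid_cylinder_radius = 4,
    head_fraction = 0.15, distal_fraction = 0.25, ulnar_fraction = 0.5,
    curvature_mode = "longitudinal"
  ), config)
  notch <- sigmoid_notch_region(
    radius, frame, curvature_threshold = cfg$curvature_threshold,
    distal_fraction = cfg$distal_fraction,
    ulnar_fraction = cfg$ulnar_fraction,
    curvature_mode = cfg$curvature_mode
  )
  margins <- sigmoid_notch_margins(radius, frame, notch$region)
  landmark_set(list(
    distal_ulnar_point = distal_ulnar_articular_point(
      ulna, frame, cfg$styloid_cylinder_radius),
    sigmoid_distal_point = notch$sigmoid_distal_point,
    palmar_margin = margins$palmar_margin,
    dorsal_margin = margins$dorsal_margin,
    notch_midpoint = margins$notch_midpoint,
    palmar_radial_corner = margins$palmar_radial_corner,
    ulnar_epicentre = ulnar_epicentre(ulna, frame),
    ulnar_styloid_tip = ulnar_styloid_tip(ulna, frame),
    ulnar_head_palmar_point = ulnar_head_palmar_point(
      ulna, frame, cfg$head_fraction, cfg$styloid_cylinder_radius)
  ), source = "auto")
}

# Deterministic lexicographic argmax: primary score, then secondary score,
# then lowest index.
pick_max2 <- function(points, score, score2) {
  ties <- which(score >= max(score) - 1e-9)
  ties <- ties[score2[ties] >= max(score2[ties]) - 1e-9]
  points[ties[1L], ]
}

# Deterministic argmax with lowest-index tie-break (warns on ties).
pick_max <- function(points, score, what) {
  m <- max(score)
  ties <- which(score >= m - 1e-12)
  if (length(ties) > 1L) {
    warning(sprintf("%s: %d tied vertices; taking the lowest index",
                    what, length(ties)))
  }
  points[ties[1L], ]
}

# Largest face-connected component among the selected vertex indices.
largest_component <- function(faces, selected) {
  sel <- sort(unique(selected))
  idx <- integer(max(faces))
  idx[sel] <- seq_along(sel)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  a <- idx[e[, 1]]; b <- idx[e[, 2]]
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  # union-find over the selected vertices
  parent <- seq_along(sel)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(sel), find, integer(1))
  counts <- table(roots)
  big <- as.integer(names(counts)[which.max(counts)])
  sel[roots == big]
}

# One-ring morphological opening of a vertex set on a mesh: erosion keeps
# vertices whose whole one-ring lies in the set, dilation re-adds set
# members adjacent to the erosion.
vertex_opening <- function(faces, set) {
  nv <- max(faces)
  in_set <- logical(nv)
  in_set[set] <- TRUE
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  # erosion: a set vertex survives if it has no neighbour outside the set
  bad <- unique(e[in_set[e[, 1]] & !in_set[e[, 2]], 1])
  eroded <- logical(nv)
  eroded[set] <- TRUE
  eroded[bad] <- FALSE
  # dilation restricted to the original set
  nb <- unique(e[eroded[e[, 1]], 2])
  out <- eroded
  out[nb[in_set[nb]]] <- TRUE
  which(out)
}

# All intersection points of an infinite line with mesh triangles.
line_mesh_intersections <- function(mesh, point, direction) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- row_cross(b - a, c_ - a)
  dir <- matrix(direction, nrow(f), 3, byrow = TRUE)
  den <- rowSums(n * dir)
  ok <- abs(den) > 1e-12 * sqrt(rowSums(n^2))
  den[!ok] <- 1
  t <- rowSums(n * sweep(a, 2, point)) / den
  x <- sweep(dir * t, 2, point, "+")
  v0 <- b - a; v1 <- c_ - a; v2 <- x - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  dd <- d00 * d11 - d01^2
  dd[abs(dd) < 1e-300] <- 1e-300
  u <- (d11 * d20 - d01 * d21) / dd
  w <- (d00 * d21 - d01 * d20) / dd
  hit <- ok & u >= -1e-12 & w >= -1e-12 & (u + w) <= 1 + 1e-12
  x[hit, , drop = FALSE]
}
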