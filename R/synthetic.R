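#' Parameters of the synthetic wrist phantom
#'
#' The generator builds five watertight bone meshes in the neutral-pose
#' radius frame (x = radial to ulnar, y = palmar to dorsal, z = proximal to
#' distal, origin at the sigmoid notch centre), with exact analytic ground
#' truth for every landmark and parameter:
#' \itemize{
#'   \item distal radius: extruded rounded-rectangular shaft with a concave
#'     sigmoid notch carved into the flat ulnar face: a circular-arc trough
#'     (longitudinal curvature exactly the reciprocal of the arc radius set
#'     by `notch_depth` and `notch_extent`) whose flat floor runs 0.4 mm
#'     past the margin columns before the end walls drop, so the margin
#'     vertices are smooth interior vertices and the curvature classifier
#'     terminates exactly at the prescribed `notch_width`; the palmar face
#'     is oblique so the palmar-radial corner is a unique vertex;
#'   \item ulna: cylindrical shaft capped by a hemispherical head with a
#'     styloid process modelled as a radial bump, its tip an exact mesh
#'     vertex; the prescribed `uv3d` fixes the head apex height relative to
#'     the notch rim, and the neutral pose places the ulnar epicentre
#'     exactly over the notch midpoint (epicentre parameter 0 by
#'     construction);
#'   \item lunate and triquetrum: spheres whose centres lie along exact
#'     head-mesh vertex directions with poles facing back, so the prescribed
#'     gaps `g_lunate`, `g_triquetrum` are met exactly by a vertex pair;
#'   \item capitate: an elongated ellipsoid whose long axis is the exact
#'     ground-truth capitate axis.
#' }
#'
#' All lengths in mm, angles in degrees.
#'
#' @param side `"right"` or `"left"` (left wrists are the mirrored twin).
#' @param uv3d Prescribed static 3-D ulnar variance (mm).
#' @param notch_width,notch_depth,notch_extent Sigmoid notch chord width,
#'   maximal depth and proximodistal extent (mm).
#' @param g_lunate,g_triquetrum Prescribed ulno-lunate / ulno-triquetral
#'   gaps (mm).
#' @param radius_length,radius_halfwidth_ru,radius_halfwidth_pd Radius shaft
#'   dimensions (mm).
#' @param palmar_tilt Obliquity of the palmar radius face (mm of rise from
#'   the radial to the ulnar corner).
#' @param ulna_length,head_radius,shaft_radius Ulna dimensions (mm).
#' @param styloid_length,styloid_polar_deg,styloid_azimuth_deg,styloid_halfwidth_deg
#'   Styloid bump: radial protrusion beyond the head sphere, polar angle
#'   from the distal pole, azimuth (0 = ulnar), angular half-width.
#' @param druj_gap Gap between the ulnar head and the flat ulnar radius
#'   face (mm).
#' @param lunate_radius,triquetrum_radius Carpal sphere radii (mm).
#' @param capitate_semiaxes Length-3 ellipsoid semi-axes (mm).
#' @param resolution Relative mesh resolution multiplier (>= 0.5).
#' @return A `wrist_params` list, validated.
#' @export
wrist_params <- function(side = "right", uv3d = -0.4, notch_width = 18,
                         notch_depth = 2.2, notch_extent = 9,
                         g_lunate = 3.2, g_triquetrum = 6.9,
                         radius_length = 85, radius_halfwidth_ru = 10,
                         radius_halfwidth_pd = 12.8, palmar_tilt = 1.5,
                         ulna_length = 95, head_radius = 10,
                         shaft_radius = 7, styloid_length = 5,
                         styloid_polar_deg = 40, styloid_azimuth_deg = 0,
                         styloid_halfwidth_deg = 12, druj_gap = 0.5,
                         lunate_radius = 6, triquetrum_radius = 5,
                         capitate_semiaxes = c(6, 6, 14), resolution = 1) {
  p <- as.list(environment())
  stopifnot(side %in% c("right", "left"), resolution >= 0.5)
  if (p$notch_depth >= 0.9 * p$radius_halfwidth_ru) {
    stop("infeasible geometry: sigmoid notch deeper than the radius")
  }
  if (p$notch_width / 2 + 1.1 > p$radius_halfwidth_pd - p$palmar_tilt) {
    stop("infeasible geometry: sigmoid notch wider than the ulnar face")
  }
  r_arc <- (p$notch_extent^2 / 4 + p$notch_depth^2) / (2 * p$notch_depth)
  if (1 / r_arc <= 0.1) {
    stop(sprintf(
      "notch arc curvature %.3f/mm does not exceed the 0.1/mm detection ",
      1 / r_arc), "threshold; deepen or shorten the notch")
  }
  if (p$g_lunate < 0 || p$g_triquetrum < 0) stop("gaps must be >= 0")
  if (p$shaft_radius >= p$head_radius) {
    stop("shaft_radius must be smaller than head_radius")
  }
  if (p$notch_width <= 0 || p$notch_extent <= 0 || p$notch_depth <= 0) {
    stop("notch dimensions must be positive")
  }
  class(p) <- "wrist_params"
  p
}

#' Generate a synthetic wrist
#'
#' Builds the five bone meshes of [wrist_params()], the radius anatomical
#' frame, the exact ground-truth landmark set and the ground-truth static
#' parameters. Ground truth is computed analytically from the construction,
#' never by the landmark detectors, so any disagreement beyond tolerance
#' indicates a pipeline defect.
#'
#' @param params A [wrist_params()] (default parameters if missing).
#' @return An object of class `synthetic_wrist`: list with `meshes` (named
#'   list: radius, ulna, lunate, triquetrum, capitate), `frame`,
#'   `landmarks` (ground truth, `source = "provided"`), `truth` (list with
#'   `uv3d`, `ucp_l`, `ucp_t`, `mru3d`, `epi3d`), `capitate_axis`,
#'   `geometry` (internal anchor points) and `params`.
#' @export
generate_wrist <- function(params = wrist_params()) {
  stopifnot(inherits(params, "wrist_params"))
  p <- params
  res <- p$resolution

  z_c <- 0
  z_rim <- z_c + p$notch_extent / 2      # distal crease apex of the notch
  z_top <- z_rim + 2                     # distal end of the radius
  z_bot <- z_top - p$radius_length

  radius <- build_radius(p, z_c, z_rim, z_top, z_bot, res)

  z_apex <- z_rim + p$uv3d               # prescribed UV fixes the apex
  head_c <- c(p$radius_halfwidth_ru + p$head_radius + p$druj_gap, 0,
              z_apex - p$head_radius)
  ulna <- build_ulna(p, head_c, z_apex, res)

  u_s <- polar_dir(p$styloid_polar_deg, p$styloid_azimuth_deg)
  u_l <- polar_dir(25, 180)
  u_t <- polar_dir(45, 310)
  lun_c <- head_c + (p$head_radius + p$g_lunate + p$lunate_radius) * u_l
  tri_c <- head_c + (p$head_radius + p$g_triquetrum + p$triquetrum_radius) * u_t
  lunate <- mesh_sphere(p$lunate_radius, lun_c,
                        n_theta = round(14 * res), n_phi = round(28 * res),
                        axis = -u_l)
  lunate$bone_label <- "lunate"
  triquetrum <- mesh_sphere(p$triquetrum_radius, tri_c,
                            n_theta = round(14 * res),
                            n_phi = round(28 * res), axis = -u_t)
  triquetrum$bone_label <- "triquetrum"

  cap_c <- c(2, 0, z_top + p$capitate_semiaxes[3] + 4)
  cap <- mesh_sphere(1, c(0, 0, 0), n_theta = round(16 * res),
                     n_phi = round(32 * res))
  cap_v <- sweep(cap$vertices %*% diag(p$capitate_semiaxes), 2, cap_c, "+")
  capitate <- triangle_mesh(cap_v, cap$faces, "capitate")

  frame <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            side = "right")

  gt <- landmark_set(list(
    distal_ulnar_point = c(head_c[1], head_c[2], z_apex),
    sigmoid_distal_point = c(p$radius_halfwidth_ru, 0, z_rim),
    palmar_margin = c(p$radius_halfwidth_ru - p$notch_depth,
                      -p$notch_width / 2, z_c),
    dorsal_margin = c(p$radius_halfwidth_ru - p$notch_depth,
                      p$notch_width / 2, z_c),
    notch_midpoint = c(p$radius_halfwidth_ru - p$notch_depth, 0, z_c),
    palmar_radial_corner = c(-p$radius_halfwidth_ru, -p$radius_halfwidth_pd,
                             z_top),
    ulnar_epicentre = c(head_c[1], head_c[2], z_apex),
    ulnar_styloid_tip = head_c + (p$head_radius + p$styloid_length) * u_s,
    ulnar_head_palmar_point = head_c + p$head_radius * c(0, -1, 0)
  ), source = "provided")

  out <- structure(list(
    meshes = list(radius = radius, ulna = ulna, lunate = lunate,
                  triquetrum = triquetrum, capitate = capitate),
    frame = frame,
    landmarks = gt,
    capitate_axis = c(0, 0, 1),
    geometry = list(head_centre = head_c, lunate_dir = u_l,
                    triquetrum_dir = u_t, ulna_axis_point = c(head_c[1],
                                                              head_c[2], 0),
                    capitate_centre = cap_c, z_rim = z_rim, z_top = z_top),
    params = p
  ), class = "synthetic_wrist")
  out$truth <- list(
    uv3d = p$uv3d,
    ucp_l = p$g_lunate,
    ucp_t = p$g_triquetrum,
    mru3d = mru_3d(gt, frame),
    epi3d = epicentre_3d(gt, frame)
  )
  if (p$side == "left") out <- mirror_wrist(out)
  out
}

#' @export
print.synthetic_wrist <- function(x, ...) {
  cat(sprintf(
    "<synthetic_wrist> side=%s uv3d=%.2f mm, gaps L=%.2f T=%.2f mm\n",
    x$params$side, x$truth$uv3d, x$truth$ucp_l, x$truth$ucp_t))
  invisible(x)
}

polar_dir <- function(polar_deg, azimuth_deg) {
  th <- polar_deg * pi / 180; ph <- azimuth_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# Distal radius: extruded cross-section with the sigmoid notch carved into
# the flat ulnar face.
build_radius <- function(p, z_c, z_rim, z_top, z_bot, res) {
  a_x <- p$radius_halfwidth_ru
  b_y <- p$radius_halfwidth_pd
  wy <- p$notch_width / 2
  hz <- p$notch_extent / 2

  # ulnar face sampling: exact columns at the margins and the midline. The
  # trough's flat plateau continues `wall_inset` beyond the margin columns
  # before the end wall drops, so the margin vertices are smooth interior
  # vertices (the crease sits on its own dedicated column, whose curvature
  # is undefined and flagged); base columns are kept clear of the band
  y_lo <- -(b_y - p$palmar_tilt)
  y_wall <- 0.2
  wall_inset <- 0.4
  yu <- seq(y_lo, b_y, length.out = round(22 * res))
  yu <- yu[abs(abs(yu) - (wy + wall_inset + y_wall / 2)) > 0.45 &
             abs(abs(yu) - wy) > 0.3]
  yu <- sort(unique(c(yu, -wy, 0, wy, -(wy + wall_inset), wy + wall_inset)))
  n_d <- round(14 * res)
  xd <- seq(a_x, -a_x, length.out = n_d)[-c(1, n_d)]
  sect <- rbind(
    cbind(a_x, yu),                                         # ulnar face
    cbind(xd, b_y),                                         # dorsal face
    cbind(-a_x, rev(seq(-b_y, b_y, length.out = round(16 * res)))),
    {                                                       # palmar face
      tt <- seq(0, 1, length.out = n_d)
      tt <- tt[-c(1, n_d)]
      cbind(-a_x + tt * 2 * a_x, -b_y + tt * (b_y + y_lo))
    }
  )

  z_grid <- sort(unique(c(
    seq(z_bot, z_c - hz - 2, by = 5 / res),
    seq(z_c - hz - 1.5, z_c + hz + 1.5, by = 0.75 / res),
    z_c - hz, z_c, z_rim, z_rim - 0.08, z_rim - 0.2, z_rim - 0.4,
    z_top, z_bot
  )))
  z_grid <- z_grid[z_grid >= z_bot & z_grid <= z_top]

  nv_ring <- nrow(sect)
  rings <- lapply(z_grid, function(zz) cbind(sect[, 1], sect[, 2], zz))
  v <- do.call(rbind, rings)

  # carve the notch: elliptical bowl on the flat ulnar face, crease boundary
  # carve the notch: a circular-arc trough along the palmar-dorsal
  # direction (longitudinal normal-section curvature exactly 1/R over the
  # whole facet), with a short end wall beyond each margin column; the
  # margin columns at +/- wy therefore carry full trough curvature while
  # the next column outward is nearly flat, so the curvature classifier's
  # region ends exactly at the prescribed margins
  R_arc <- (hz^2 + p$notch_depth^2) / (2 * p$notch_depth)
  on_face <- abs(v[, 1] - a_x) < 1e-9
  s_env <- pmax(0, pmin(1, (wy + wall_inset + y_wall - abs(v[, 2])) / y_wall))
  in_z <- abs(v[, 3] - z_c) <= hz + 1e-12
  inside <- on_face & in_z & s_env > 0
  depth <- s_env * (sqrt(pmax(0, R_arc^2 - (v[, 3] - z_c)^2)) -
                      sqrt(R_arc^2 - hz^2))
  v[inside, 1] <- v[inside, 1] - depth[inside]

  f <- extrusion_faces(length(z_grid), nv_ring)
  first <- seq_len(nv_ring)
  last <- (length(z_grid) - 1L) * nv_ring + seq_len(nv_ring)
  bot <- cap_fan(sect, z_bot, nrow(v), first, outward_up = FALSE)
  v <- rbind(v, bot$vertices)
  f <- rbind(f, bot$faces)
  top <- cap_fan(sect, z_top, nrow(v), last, outward_up = TRUE)
  v <- rbind(v, top$vertices)
  f <- rbind(f, top$faces)
  triangle_mesh(v, f, "radius")
}

# End cap with interior rings (shrunken copies of the section polygon), so
# cap surfaces carry enough vertices to constrain registration along the
# bone axis. `rim_ids` are the indices of the existing boundary ring.
cap_fan <- function(sect, z, n_before, rim_ids, outward_up) {
  ctr <- colMeans(sect)
  scales <- c(0.62, 0.3)
  nv_ring <- nrow(sect)
  rings <- lapply(scales, function(s) {
    cbind(ctr[1] + s * (sect[, 1] - ctr[1]),
          ctr[2] + s * (sect[, 2] - ctr[2]), z)
  })
  verts <- rbind(do.call(rbind, rings), c(ctr, z))
  ids <- lapply(seq_along(scales), function(i) {
    n_before + (i - 1L) * nv_ring + seq_len(nv_ring)
  })
  centre_id <- n_before + length(scales) * nv_ring + 1L
  j <- seq_len(nv_ring)
  j2 <- j %% nv_ring + 1L
  band <- function(outer_ids, inner_ids) {
    # viewed from +z the section is CCW; an upward-facing cap keeps that
    # orientation, a downward-facing cap reverses it
    if (outward_up) {
      rbind(cbind(outer_ids[j], outer_ids[j2], inner_ids[j2]),
            cbind(outer_ids[j], inner_ids[j2], inner_ids[j]))
    } else {
      rbind(cbind(outer_ids[j], inner_ids[j2], outer_ids[j2]),
            cbind(outer_ids[j], inner_ids[j], inner_ids[j2]))
    }
  }
  faces <- band(rim_ids, ids[[1]])
  if (length(scales) > 1L) {
    for (i in seq_len(length(scales) - 1L)) {
      faces <- rbind(faces, band(ids[[i]], ids[[i + 1L]]))
    }
  }
  inner <- ids[[length(scales)]]
  fan <- if (outward_up) {
    cbind(centre_id, inner[j], inner[j2])
  } else {
    cbind(centre_id, inner[j2], inner[j])
  }
  list(vertices = verts, faces = rbind(faces, fan))
}

# Quad strip faces between consecutive rings of an extrusion (CCW sections).
extrusion_faces <- function(n_rings, nv_ring) {
  f <- vector("list", n_rings - 1L)
  j <- seq_len(nv_ring)
  j2 <- j %% nv_ring + 1L
  for (i in seq_len(n_rings - 1L)) {
    a <- (i - 1L) * nv_ring + j
    a2 <- (i - 1L) * nv_ring + j2
    b <- i * nv_ring + j
    b2 <- i * nv_ring + j2
    f[[i]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  do.call(rbind, f)
}

# Ulna: shaft + hemispherical head (surface of revolution) + styloid bump.
build_ulna <- function(p, head_c, z_apex, res) {
  r_h <- p$head_radius; r_s <- p$shaft_radius
  z_hc <- head_c[3]
  z_join <- z_hc - sqrt(r_h^2 - r_s^2)
  z_bot <- z_apex - p$ulna_length

  phi <- seq(0, 350, by = 10 / res) * pi / 180
  n_phi <- length(phi)
  shaft_z <- sort(unique(c(seq(z_bot, z_join - 2, by = 5 / res), z_join)))
  shaft_z <- shaft_z[shaft_z <= z_join]
  th_join <- acos((z_join - z_hc) / r_h) * 180 / pi  # polar angle at join
  head_th <- sort(unique(c(seq(5, floor(th_join), by = 5 / res),
                           p$styloid_polar_deg, 25, 45)), decreasing = TRUE)
  head_th <- head_th[head_th < th_join - 1e-9]

  rings <- list()
  for (zz in shaft_z) {
    rings[[length(rings) + 1L]] <-
      cbind(head_c[1] + r_s * cos(phi), head_c[2] + r_s * sin(phi), zz)
  }
  for (th in head_th) {
    t_ <- th * pi / 180
    rings[[length(rings) + 1L]] <-
      cbind(head_c[1] + r_h * sin(t_) * cos(phi),
            head_c[2] + r_h * sin(t_) * sin(phi),
            z_hc + r_h * cos(t_))
  }
  v <- do.call(rbind, rings)
  n_rings <- length(rings)
  f <- extrusion_faces(n_rings, n_phi)
  apex_id <- nrow(v) + 1L
  bot_id <- nrow(v) + 2L
  v <- rbind(v, c(head_c[1], head_c[2], z_hc + r_h),
             c(head_c[1], head_c[2], z_bot))
  j <- seq_len(n_phi)
  j2 <- j %% n_phi + 1L
  last <- (n_rings - 1L) * n_phi + j
  f <- rbind(
    f,
    cbind(apex_id, last, last[j2]),      # apex fan
    cbind(bot_id, j[j2], j)              # bottom cap
  )

  # styloid bump: radial displacement of head vertices near the styloid
  # direction; the tip is the exact vertex at that direction
  u_s <- polar_dir(p$styloid_polar_deg, p$styloid_azimuth_deg)
  rel <- sweep(v, 2, head_c)
  rr <- sqrt(rowSums(rel^2))
  on_head <- v[, 3] > z_join + 1e-9 & abs(rr - r_h) < 1e-6
  dirs <- rel / rr
  psi <- acos(pmin(1, pmax(-1, as.numeric(dirs %*% u_s)))) * 180 / pi
  bump <- on_head & psi < p$styloid_halfwidth_deg
  amp <- p$styloid_length *
    cos(pi / 2 * psi / p$styloid_halfwidth_deg)^2
  v[bump, ] <- sweep(dirs[bump, , drop = FALSE] * (r_h + amp[bump]), 2,
                     head_c, "+")

  triangle_mesh(v, f, "ulna")
}

# Mirror a right-construction wrist into its left twin.
mirror_wrist <- function(w) {
  w$meshes <- lapply(w$meshes, mesh_mirror)
  mirror_pt <- function(pt) pt * c(-1, 1, 1)
  w$landmarks <- landmark_set(lapply(w$landmarks$points, mirror_pt),
                              source = "provided")
  w$frame <- structure(list(origin = c(0, 0, 0), e_ru = c(-1, 0, 0),
                            e_pd = c(0, 1, 0), e_lon = c(0, 0, 1),
                            side = "left"),
                       class = "anatomical_frame")
  w$geometry <- lapply(w$geometry, function(g) {
    if (is.numeric(g) && length(g) == 3) mirror_pt(g) else g
  })
  w$capitate_axis <- w$capitate_axis
  w
}
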