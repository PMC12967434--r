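#' Motion parameters for a simulated wrist sequence
#'
#' Describes one dynamic acquisition of the phantom: the movement (FE =
#' flexion-extension, RUD = radioulnar deviation, PS =
#' pronation-supination), its angular amplitude, the number of reconstructed
#' frames and the frame rate (default 10 frames/s, the dynamic-CT
#' reconstruction rate), plus the coupling functions that prescribe how the
#' DRUJ translates during the movement:
#' \describe{
#'   \item{uv_drift(theta)}{change of 3-D ulnar variance (mm) relative to
#'     neutral, realized by proximodistal translation of the radius.}
#'   \item{dp_translation(theta)}{dorso-palmar DRUJ translation (mm),
#'     positive = radius dorsal, realized by translating the radius along
#'     its (instantaneous) palmar-dorsal axis.}
#'   \item{approach_l(theta), approach_t(theta)}{change of the ulno-lunate /
#'     ulno-triquetral gap (mm) relative to neutral, realized by translating
#'     the carpal along its exact gap line.}
#' }
#' Defaults (used when a function is `NULL`) are calibrated so that a
#' default cohort reproduces plausible in-vivo magnitudes: angular
#' amplitudes follow the extreme positions reported for healthy wrists
#' (flexion 40 to extension 60, ulnar 25 to radial 10, pronation 50 to
#' supination 50 degrees), the PS dorso-palmar translation spans 15.2% of
#' notch width, FE/RUD span 7.7% / 9.3%, and the carpal approach functions
#' interpolate the healthy-cohort proximity values.
#'
#' @param movement `"FE"`, `"RUD"` or `"PS"`.
#' @param amplitude Length-2 angle range in degrees (movement-specific
#'   default).
#' @param n_frames Number of frames (default 11).
#' @param frame_rate Frames per second (default 10).
#' @param uv_drift,dp_translation,approach_l,approach_t Coupling functions
#'   of the wrist angle (degrees), or `NULL` for the movement default.
#' @param coupling_scale Scalar multiplying all default coupling amplitudes
#'   (per-wrist variability in cohort simulations).
#' @return A `motion_params` list.
#' @export
motion_params <- function(movement, amplitude = NULL, n_frames = 11L,
                          frame_rate = 10, uv_drift = NULL,
                          dp_translation = NULL, approach_l = NULL,
                          approach_t = NULL, coupling_scale = 1) {
  movement <- match.arg(movement, c("FE", "RUD", "PS"))
  feasible <- list(FE = c(-90, 90), RUD = c(-50, 40), PS = c(-95, 95))
  if (is.null(amplitude)) {
    amplitude <- switch(movement,
      FE = c(-40, 60), RUD = c(-25, 10), PS = c(-50, 50))
  }
  amplitude <- as.numeric(amplitude)
  stopifnot(length(amplitude) == 2, amplitude[1] < amplitude[2])
  lim <- feasible[[movement]]
  if (amplitude[1] < lim[1] || amplitude[2] > lim[2]) {
    stop(sprintf("amplitude outside the feasible %s range [%g, %g] deg",
                 movement, lim[1], lim[2]))
  }
  if (n_frames < 2L) stop("n_frames must be >= 2")
  structure(list(
    movement = movement, amplitude = amplitude, n_frames = as.integer(n_frames),
    frame_rate = frame_rate, uv_drift = uv_drift,
    dp_translation = dp_translation, approach_l = approach_l,
    approach_t = approach_t, coupling_scale = coupling_scale
  ), class = "motion_params")
}

default_couplings <- function(motion, notch_width) {
  cs <- motion$coupling_scale
  w <- notch_width
  m <- motion$movement
  list(
    uv_drift = switch(m,
      FE = function(th) cs * 0.6 * (th / 60)^2,
      RUD = function(th) cs * (0.4 / 35) * th,
      PS = function(th) cs * -1.1 * (th / 50)^2),
    dp_translation = switch(m,
      FE = function(th) cs * 0.077 * w * th / 100,
      RUD = function(th) cs * 0.093 * w * th / 35,
      PS = function(th) cs * 0.152 * w * th / 100),
    approach_l = switch(m,
      FE = function(th) cs * -0.010 * th,
      RUD = function(th) cs * -(0.4 / 35) * th,
      PS = function(th) cs * 0.001 * th),
    approach_t = switch(m,
      FE = function(th) cs * -0.019 * th,
      RUD = function(th) cs * (4.4 / 35) * th,
      PS = function(th) cs * 0.019 * th)
  )
}

#' Simulate a dynamic sequence of the synthetic wrist
#'
#' Poses the phantom through the movement with per-frame rigid transforms
#' realizing the wrist angle and the prescribed couplings, and exports the
#' exact analytic ground-truth parameter series (computed from the
#' transformed ground-truth landmarks and gap constructions, never from the
#' detectors).
#'
#' Motion model: FE and RUD rotate the capitate about the radius frame's
#' radioulnar / palmar-dorsal axis through the capitate centre; PS rotates
#' the radius (and capitate) about the ulna's longitudinal axis. Ulnar
#' variance drift and dorso-palmar translation move the radius; the lunate
#' and triquetrum translate along their exact gap lines so the prescribed
#' proximities hold to machine precision.
#'
#' @param wrist A [generate_wrist()] phantom (right-handed; normalize left
#'   wrists first).
#' @param motion A [motion_params()].
#' @return An object of class `dynamic_sequence`: `movement`, `frame_rate`,
#'   `thetas`, `poses` (per frame, named list of [rigid_transform()] per
#'   bone), `static` (the wrist), `targets` (`NULL` until [degrade()]),
#'   and `truth` (ground-truth parameter data frame).
#' @export
simulate_motion <- function(wrist, motion) {
  stopifnot(inherits(wrist, "synthetic_wrist"),
            inherits(motion, "motion_params"))
  if (wrist$frame$side != "right") {
    stop("simulate_motion expects a right-normalized wrist")
  }
  p <- wrist$params
  cpl <- default_couplings(motion, p$notch_width)
  for (nm in names(cpl)) {
    if (!is.null(motion[[nm]])) cpl[[nm]] <- motion[[nm]]
  }
  thetas <- seq(motion$amplitude[1], motion$amplitude[2],
                length.out = motion$n_frames)
  # feasibility: gaps must stay positive over the whole trajectory
  g_l <- wrist$truth$ucp_l + vapply(thetas, cpl$approach_l, numeric(1))
  g_t <- wrist$truth$ucp_t + vapply(thetas, cpl$approach_t, numeric(1))
  if (any(g_l < 0.05) || any(g_t < 0.05)) {
    stop("carpal approach would close or invert an ulnocarpal gap")
  }

  frame <- wrist$frame
  cap_c <- wrist$geometry$capitate_centre
  ax_pt <- wrist$geometry$ulna_axis_point
  ident <- rigid_transform()

  poses <- vector("list", motion$n_frames)
  truth <- vector("list", motion$n_frames)
  for (i in seq_along(thetas)) {
    th <- thetas[i]
    uv_d <- cpl$uv_drift(th)
    dp <- cpl$dp_translation(th)
    if (motion$movement == "PS") {
      R <- rotation_about_axis(frame$e_lon, th)
      t_rot <- ax_pt - as.numeric(R %*% ax_pt)
      e_pd_rot <- as.numeric(R %*% frame$e_pd)
      t_full <- t_rot + dp * e_pd_rot - uv_d * frame$e_lon
      T_rad <- rigid_transform(R, t_full)
      T_cap <- T_rad
    } else {
      T_rad <- rigid_transform(diag(3), dp * frame$e_pd - uv_d * frame$e_lon)
      axis <- if (motion$movement == "FE") -frame$e_ru else -frame$e_pd
      Rc <- rotation_about_axis(axis, th)
      T_cap <- rigid_transform(Rc, cap_c - as.numeric(Rc %*% cap_c))
    }
    T_lun <- rigid_transform(diag(3),
                             cpl$approach_l(th) * wrist$geometry$lunate_dir)
    T_tri <- rigid_transform(diag(3),
                             cpl$approach_t(th) * wrist$geometry$triquetrum_dir)
    poses[[i]] <- list(radius = T_rad, ulna = ident, lunate = T_lun,
                       triquetrum = T_tri, capitate = T_cap)

    # analytic ground truth at this frame; the head palmar point is an
    # extremum in the instantaneous frame (sphere pole), not a transported
    # material point
    lm_t <- transport_landmarks(wrist$landmarks, poses[[i]])
    frame_t <- frame_transform(frame, T_rad)
    hc_t <- transform_points(poses[[i]]$ulna, wrist$geometry$head_centre)
    lm_t$points$ulnar_head_palmar_point <-
      hc_t - p$head_radius * frame_t$e_pd
    cap_axis_t <- as.numeric(T_cap$rotation %*% wrist$capitate_axis)
    ang <- switch(motion$movement,
      FE = ,
      RUD = wrist_angle(motion$movement, frame_t, capitate_axis = cap_axis_t),
      PS = wrist_angle("PS", frame_t,
                       styloid_tip = lm_t$points$ulnar_styloid_tip,
                       epicentre = lm_t$points$ulnar_epicentre))
    truth[[i]] <- data.frame(
      frame_index = i,
      time_s = (i - 1) / motion$frame_rate,
      movement = motion$movement,
      wrist_angle_deg = ang,
      uv3d_mm = wrist$truth$uv3d + uv_d,
      ucp_l_mm = g_l[i],
      ucp_t_mm = g_t[i],
      mru3d_pct = mru_3d(lm_t, frame_t),
      epi3d_pct = epicentre_3d(lm_t, frame_t)
    )
  }
  truth <- delta_series(do.call(rbind, truth))
  structure(list(
    movement = motion$movement, frame_rate = motion$frame_rate,
    thetas = thetas, poses = poses, static = wrist, targets = NULL,
    truth = truth, motion = motion
  ), class = "dynamic_sequence")
}

#' @export
print.dynamic_sequence <- function(x, ...) {
  cat(sprintf("<dynamic_sequence> %s, %d frames at %g Hz, angles %g..%g deg%s\n",
              x$movement, length(x$thetas), x$frame_rate,
              min(x$thetas), max(x$thetas),
              if (is.null(x$targets)) "" else " (with frame targets)"))
  invisible(x)
}

# Transport a landmark set by per-bone transforms.
transport_landmarks <- function(landmarks, pose) {
  bone_of <- c(
    distal_ulnar_point = "ulna", sigmoid_distal_point = "radius",
    palmar_margin = "radius", dorsal_margin = "radius",
    notch_midpoint = "radius", palmar_radial_corner = "radius",
    ulnar_epicentre = "ulna", ulnar_styloid_tip = "ulna",
    ulnar_head_palmar_point = "ulna"
  )
  pts <- lapply(names(landmarks$points), function(nm) {
    transform_points(pose[[bone_of[[nm]]]], landmarks$points[[nm]])
  })
  names(pts) <- names(landmarks$points)
  landmark_set(pts, source = landmarks$source)
}

#' Degrade a sequence into noisy per-frame registration targets
#'
#' Emulates dynamic-scan quality: for every frame and bone, the posed static
#' mesh vertices are optionally decimated and perturbed with isotropic
#' Gaussian jitter, producing the per-frame point-cloud targets that
#' [track_sequence()] registers against. Ground truth is untouched. Fully
#' seeded and reproducible.
#'
#' @param seq A [simulate_motion()] sequence.
#' @param sigma Vertex jitter standard deviation in mm (0.25 is about half
#'   the dynamic-scan voxel size).
#' @param decimation Fraction of vertices to drop (0 keeps all).
#' @param seed Integer seed.
#' @return The sequence with a `targets` element: per frame, a named list
#'   of point matrices.
#' @export
degrade <- function(seq, sigma = 0.25, decimation = 0, seed = 1L) {
  stopifnot(inherits(seq, "dynamic_sequence"), sigma >= 0,
            decimation >= 0, decimation < 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  seq$targets <- lapply(seq_along(seq$poses), function(i) {
    pose <- seq$poses[[i]]
    out <- lapply(names(seq$static$meshes), function(bone) {
      v <- transform_points(pose[[bone]], seq$static$meshes[[bone]]$vertices)
      if (decimation > 0) {
        keep <- sort(sample.int(nrow(v), ceiling((1 - decimation) * nrow(v))))
        if (length(keep) < 100L) {
          stop("decimation leaves fewer than 100 vertices for the ", bone)
        }
        v <- v[keep, , drop = FALSE]
      }
      if (sigma > 0) {
        v <- v + matrix(stats::rnorm(length(v), sd = sigma), nrow(v), 3)
      }
      v
    })
    names(out) <- names(seq$static$meshes)
    out
  })
  seq
}
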