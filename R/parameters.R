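#' 3-D ulnar variance
#'
#' Height difference along the longitudinal axis between the most distal
#' point of the ulnar head articular surface (styloid removed) and the most
#' distal point of the radial sigmoid notch, both expressed in the radius
#' frame. Positive when the ulna reaches more distally than the notch
#' ("ulna-plus").
#'
#' @param distal_ulnar_point,sigmoid_distal_point Length-3 points (mm), same
#'   world coordinates.
#' @param frame The radius [anatomical_frame()].
#' @return Ulnar variance in mm (signed).
#' @export
ulnar_variance_3d <- function(distal_ulnar_point, sigmoid_distal_point,
                              frame) {
  sum((distal_ulnar_point - sigmoid_distal_point) * frame$e_lon)
}

#' Ulnocarpal proximity
#'
#' Shortest 3-D surface distance between the ulna and a carpal bone (lunate:
#' UcP-L; triquetrum: UcP-T), with the realizing site pair so that drift of
#' the measurement location across wrist positions is observable.
#' Interpenetrating surfaces report 0 mm with a warning.
#'
#' @param ulna Ulna [triangle_mesh()].
#' @param carpal Lunate or triquetrum [triangle_mesh()].
#' @return List with `distance` (mm), `site_ulna`, `site_carpal` (points).
#' @export
ulnocarpal_proximity <- function(ulna, carpal) {
  if (!is.na(carpal$bone_label) &&
      !carpal$bone_label %in% c("lunate", "triquetrum")) {
    stop("carpal must be the lunate or the triquetrum")
  }
  md <- min_distance(ulna, carpal)
  if (md$intersecting) {
    warning("ulna and carpal surfaces interpenetrate; proximity is 0 mm")
  }
  list(distance = md$distance, site_ulna = md$point_a,
       site_carpal = md$point_b)
}

#' 3-D modified radioulnar line method
#'
#' Ulnar head protrusion beyond the palmar-radial line as a percentage of
#' sigmoid notch width: the signed distance from the most palmar point of
#' the ulnar head to the line through the palmar-radial corner and the
#' palmar notch margin, measured in the axial plane of the radius frame
#' (the plane of the axial view in which the radioulnar line is defined;
#' landmarks are projected along `e_lon` first, which also makes the
#' response to a dorso-palmar DRUJ translation exactly linear). The sign
#' follows the convention that dorsal dislocation of the radius relative to
#' the ulnar head is positive — equivalently, the value is positive when
#' the ulnar head palmar point protrudes palmarly beyond the palmar-radial
#' line.
#'
#' @param landmarks A [landmark_set()].
#' @param frame The radius [anatomical_frame()].
#' @return Signed percentage of notch width.
#' @export
mru_3d <- function(landmarks, frame) {
  p <- landmarks$points
  w <- notch_width(p)
  ax <- function(x) c(sum(x * frame$e_ru), sum(x * frame$e_pd))
  a <- ax(p$ulnar_head_palmar_point)
  b <- ax(p$palmar_radial_corner)
  c_ <- ax(p$palmar_margin)
  u <- (c_ - b) / sqrt(sum((c_ - b)^2))
  rel <- a - b
  # signed in-plane offset from the line: positive towards palmar (-e_pd)
  n_line <- c(u[2], -u[1]) # normal of the line within the axial plane
  if (n_line[2] > 0) n_line <- -n_line # orient palmar
  100 * sum(rel * n_line) / w
}

#' 3-D epicentre method
#'
#' Projects the ulnar epicentre onto the sigmoid notch chord (palmar to
#' dorsal margin) and reports the signed offset of the projection from the
#' chord midpoint as a percentage of notch width. Positive when the
#' projection is displaced towards the palmar margin (relative dorsal
#' dislocation of the radius), negative towards the dorsal margin. A
#' projection farther than 150% of the width from the midpoint raises a
#' gross-dislocation warning.
#'
#' @param landmarks A [landmark_set()].
#' @param frame The radius [anatomical_frame()]. Unused by the projection
#'   itself (the chord fixes the direction) but kept for interface symmetry
#'   with [mru_3d()].
#' @return Signed percentage of notch width.
#' @export
epicentre_3d <- function(landmarks, frame) {
  p <- landmarks$points
  w <- notch_width(p)
  u_palmar <- (p$palmar_margin - p$dorsal_margin) / w
  s <- sum((p$ulnar_epicentre - p$notch_midpoint) * u_palmar)
  if (abs(s) > 1.5 * w) {
    warning("epicentre projects far outside the sigmoid notch segment ",
            "(gross dislocation?)")
  }
  100 * s / w
}

notch_width <- function(p) {
  w <- sqrt(sum((p$palmar_margin - p$dorsal_margin)^2))
  if (w <= .Machine$double.eps) stop("sigmoid notch width is zero")
  w
}

#' Wrist angle per movement
#'
#' Signed wrist angle in degrees: the sagittal capitoradial (CR) angle during
#' flexion-extension (`"FE"`), the coronal CR angle during radioulnar
#' deviation (`"RUD"`), and the ulnoradial angle in the axial plane during
#' pronation-supination (`"PS"`). The two axes are projected onto the named
#' plane of the radius frame (sagittal = `e_pd`/`e_lon`, coronal =
#' `e_ru`/`e_lon`, axial = `e_ru`/`e_pd`) and the signed angle between the
#' projections is returned.
#'
#' Sign conventions (right-hand convention after side normalization):
#' extension, radial deviation and supination positive; flexion, ulnar
#' deviation and pronation negative. For PS the ulnar axis is the line
#' through the ulnar styloid tip and the ulnar epicentre, taken in the
#' epicentre-to-styloid sense so that its axial projection points ulnarly
#' and the neutral ulnoradial angle is near zero.
#'
#' @param movement `"FE"`, `"RUD"` or `"PS"`.
#' @param frame The radius [anatomical_frame()] (supplies the radius long
#'   axis `e_lon`, the mediolateral axis `e_ru` and the projection planes).
#' @param capitate_axis Length-3 capitate long-axis direction (FE/RUD).
#' @param styloid_tip,epicentre Length-3 points defining the ulnar axis (PS).
#' @param degenerate_warn_deg Warn when a projected axis lies within this
#'   many degrees of the plane normal (near-degenerate projection).
#' @return Signed angle in degrees.
#' @export
wrist_angle <- function(movement, frame, capitate_axis = NULL,
                        styloid_tip = NULL, epicentre = NULL,
                        degenerate_warn_deg = 5) {
  movement <- match.arg(movement, c("FE", "RUD", "PS"))
  if (movement %in% c("FE", "RUD")) {
    if (is.null(capitate_axis)) stop("FE/RUD need the capitate axis")
    normal <- if (movement == "FE") frame$e_ru else frame$e_pd
    ref <- frame$e_lon
    mov <- as.numeric(capitate_axis)
    # extension tilts the capitate towards +e_pd -> positive about -e_ru;
    # radial deviation tilts towards -e_ru -> positive about -e_pd
    sign_axis <- if (movement == "FE") -frame$e_ru else -frame$e_pd
  } else {
    if (is.null(styloid_tip) || is.null(epicentre)) {
      stop("PS needs the ulnar styloid tip and the ulnar epicentre")
    }
    normal <- frame$e_lon
    ref <- as.numeric(styloid_tip) - as.numeric(epicentre)
    mov <- frame$e_ru
    # supination rotates e_ru about +e_lon (right-hand rule)
    sign_axis <- frame$e_lon
  }
  pr <- function(x) x - sum(x * normal) * normal
  ref_p <- pr(ref); mov_p <- pr(mov)
  check_degenerate <- function(raw, proj) {
    lr <- sqrt(sum(raw^2)); lp <- sqrt(sum(proj^2))
    if (lp < lr * sin(degenerate_warn_deg * pi / 180)) {
      warning("axis nearly perpendicular to the projection plane; ",
              "wrist angle is ill-conditioned")
    }
  }
  check_degenerate(ref, ref_p)
  check_degenerate(mov, mov_p)
  crossv <- c(
    ref_p[2] * mov_p[3] - ref_p[3] * mov_p[2],
    ref_p[3] * mov_p[1] - ref_p[1] * mov_p[3],
    ref_p[1] * mov_p[2] - ref_p[2] * mov_p[1]
  )
  atan2(sum(crossv * sign_axis), sum(ref_p * mov_p)) * 180 / pi
}

#' Delta values relative to the neutral wrist position
#'
#' Adds delta columns (`d_uv3d_mm`, `d_mru3d_pct`, `d_epi3d_pct`) to a
#' parameter time series: each value minus its value at the neutral frame.
#' The neutral frame is the frame with minimum absolute wrist angle (ties go
#' to the earliest frame); its deltas are exactly zero.
#'
#' @param series A parameter time-series data frame (see
#'   [evaluate_sequence()]) with at least `wrist_angle_deg` and the
#'   parameter columns.
#' @param neutral_frame Optional row index overriding neutral-frame
#'   selection.
#' @return The series with delta columns and attribute `neutral_frame`.
#' @export
delta_series <- function(series, neutral_frame = NULL) {
  if (!nrow(series)) stop("empty parameter series")
  if (is.null(neutral_frame)) {
    neutral_frame <- which.min(abs(series$wrist_angle_deg))
  }
  map <- c(d_uv3d_mm = "uv3d_mm", d_mru3d_pct = "mru3d_pct",
           d_epi3d_pct = "epi3d_pct")
  for (dcol in names(map)) {
    src <- map[[dcol]]
    if (src %in% names(series)) {
      series[[dcol]] <- series[[src]] - series[[src]][neutral_frame]
      series[[dcol]][neutral_frame] <- 0
    }
  }
  attr(series, "neutral_frame") <- neutral_frame
  series
}

#' Classify ulnar variance
#'
#' Neutral when |UV| < 1 mm; the 1 mm boundary itself is assigned outward
#' (non-neutral).
#'
#' @param uv3d Numeric vector of ulnar variance values (mm).
#' @return Character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
classify_uv <- function(uv3d) {
  stopifnot(all(is.finite(uv3d)))
  ifelse(abs(uv3d) < 1, "neutral", ifelse(uv3d <= -1, "negative", "positive"))
}
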