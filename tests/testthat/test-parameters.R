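frame0 <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

# landmark set with simple axis-aligned geometry: notch chord 20 mm along
# the palmar-dorsal axis, palmar-radial line along the radioulnar axis
toy_landmarks <- function(head_palmar = c(0, -12, 0),
                          epicentre = c(15, 0, 0)) {
  landmark_set(list(
    distal_ulnar_point = c(15, 0, 1),
    sigmoid_distal_point = c(10, 0, 1.4),
    palmar_margin = c(10, -10, 0),
    dorsal_margin = c(10, 10, 0),
    notch_midpoint = c(10, 0, 0),
    palmar_radial_corner = c(-10, -10, 0),
    ulnar_epicentre = epicentre,
    ulnar_styloid_tip = c(25, 0, 2),
    ulnar_head_palmar_point = head_palmar
  ), source = "provided")
}

test_that("3-D ulnar variance is the signed height difference along the
           longitudinal axis", {
  expect_equal(ulnar_variance_3d(c(3, 5, 9.6), c(1, 2, 10), frame0), -0.4)
  expect_equal(ulnar_variance_3d(c(3, 5, 10), c(1, 2, 10), frame0), 0)
  # only the longitudinal component counts
  expect_equal(ulnar_variance_3d(c(50, -4, 12), c(0, 0, 10), frame0), 2)
})

test_that("ulnar variance classification uses the neutral band |uv| < 1 mm
           with the boundary assigned outward", {
  expect_identical(classify_uv(c(-0.4, 0, 0.999)),
                   c("neutral", "neutral", "neutral"))
  expect_identical(classify_uv(c(1, -1)), c("positive", "negative"))
  expect_identical(classify_uv(-2.3), "negative")
  expect_error(classify_uv(NaN))
})

test_that("modified radioulnar line: zero on the line, +10% for a 2 mm
           palmar protrusion at 20 mm notch width", {
  # head palmar point exactly on the palmar-radial line (y = -10)
  on_line <- toy_landmarks(head_palmar = c(0, -10, 0))
  expect_equal(mru_3d(on_line, frame0), 0, tolerance = 1e-12)
  # displaced 2 mm palmarly beyond the line: ulna palmar = radius
  # relatively dorsal = positive
  palmar <- toy_landmarks(head_palmar = c(0, -12, 0))
  expect_equal(mru_3d(palmar, frame0), 10)
  dorsal <- toy_landmarks(head_palmar = c(0, -8, 0))
  expect_equal(mru_3d(dorsal, frame0), -10)
})

test_that("epicentre method: zero at the midpoint, +50% at the palmar
           margin, warning far outside the notch", {
  centred <- toy_landmarks(epicentre = c(15, 0, 0))
  expect_equal(epicentre_3d(centred, frame0), 0)
  at_palmar <- toy_landmarks(epicentre = c(15, -10, 3))
  expect_equal(epicentre_3d(at_palmar, frame0), 50)
  at_dorsal <- toy_landmarks(epicentre = c(15, 10, 3))
  expect_equal(epicentre_3d(at_dorsal, frame0), -50)
  expect_warning(epicentre_3d(toy_landmarks(epicentre = c(15, -45, 0)),
                              frame0), "outside")
})

test_that("zero notch width is rejected", {
  lm <- toy_landmarks()
  lm$points$dorsal_margin <- lm$points$palmar_margin
  lm$points$notch_midpoint <- lm$points$palmar_margin
  expect_error(mru_3d(lm, frame0), "width")
  expect_error(epicentre_3d(lm, frame0), "width")
})

test_that("wrist angles decompose by plane with the documented signs", {
  # capitate parallel to the radius axis: both CR angles zero
  expect_equal(wrist_angle("FE", frame0, capitate_axis = c(0, 0, 1)), 0)
  expect_equal(wrist_angle("RUD", frame0, capitate_axis = c(0, 0, 1)), 0)
  # 30 degrees towards dorsal, purely sagittal: extension +30, coronal 0
  tilt <- c(0, sin(30 * pi / 180), cos(30 * pi / 180))
  expect_equal(wrist_angle("FE", frame0, capitate_axis = tilt), 30,
               tolerance = 1e-9)
  expect_equal(wrist_angle("RUD", frame0, capitate_axis = tilt), 0,
               tolerance = 1e-9)
  # flexion (palmar tilt) is negative; radial deviation positive
  expect_lt(wrist_angle("FE", frame0, capitate_axis = c(0, -0.5, 0.87)), 0)
  expect_gt(wrist_angle("RUD", frame0, capitate_axis = c(-0.5, 0, 0.87)), 0)
  # PS: rotating e_ru by +theta about e_lon reads as +theta (supination)
  lm <- toy_landmarks()
  for (th in c(-50, -10, 25)) {
    R <- rotation_about_axis(c(0, 0, 1), th)
    fr <- frame_transform(frame0, rigid_transform(R, c(0, 0, 0)))
    ang <- wrist_angle("PS", fr,
                       styloid_tip = lm$points$ulnar_styloid_tip,
                       epicentre = lm$points$ulnar_epicentre)
    expect_equal(ang, th, tolerance = 1e-9)
  }
  expect_warning(
    wrist_angle("FE", frame0, capitate_axis = c(0.999, 0, 0.02)),
    "ill-conditioned")
})

test_that("delta series vanish exactly at the neutral frame", {
  s <- data.frame(wrist_angle_deg = c(-10, 1, 12),
                  uv3d_mm = c(1.0, 1.5, 0.8),
                  mru3d_pct = c(5, 5, 5), epi3d_pct = c(0, 2, 4))
  d <- delta_series(s)
  expect_identical(attr(d, "neutral_frame"), 2L)
  expect_identical(d$d_uv3d_mm[2], 0)
  expect_equal(d$d_uv3d_mm, c(-0.5, 0, -0.7))
  expect_equal(d$d_mru3d_pct, c(0, 0, 0))
  # explicit neutral override and the documented example
  d0 <- delta_series(s, neutral_frame = 1)
  expect_equal(d0$d_uv3d_mm, c(0, 0.5, -0.2))
  expect_error(delta_series(s[0, ]), "empty")
})

test_that("pure translations obey the linear-response laws", {
  w <- default_wrist()
  lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  W <- sqrt(sum((lm$points$palmar_margin - lm$points$dorsal_margin)^2))
  base_mru <- mru_3d(lm, w$frame)
  base_epi <- epicentre_3d(lm, w$frame)
  base_uv <- ulnar_variance_3d(lm$points$distal_ulnar_point,
                               lm$points$sigmoid_distal_point, w$frame)
  shift_ulna <- function(lm, dvec) {
    pts <- lm$points
    for (nm in c("distal_ulnar_point", "ulnar_epicentre",
                 "ulnar_styloid_tip", "ulnar_head_palmar_point")) {
      pts[[nm]] <- pts[[nm]] + dvec
    }
    landmark_set(pts, source = "provided")
  }
  for (t in c(0.5, 1, 2)) {
    lm_t <- shift_ulna(lm, t * w$frame$e_pd) # ulna dorsal
    expect_lt(abs(mru_3d(lm_t, w$frame) - base_mru + 100 * t / W), 1)
    expect_lt(abs(epicentre_3d(lm_t, w$frame) - base_epi + 100 * t / W),
              1e-9)
  }
  for (d in c(0.5, 2)) {
    lm_d <- shift_ulna(lm, d * w$frame$e_lon)
    uv <- ulnar_variance_3d(lm_d$points$distal_ulnar_point,
                            lm_d$points$sigmoid_distal_point, w$frame)
    expect_equal(uv - base_uv, d, tolerance = 1e-9)
    expect_equal(mru_3d(lm_d, w$frame), base_mru, tolerance = 0.5)
    expect_equal(epicentre_3d(lm_d, w$frame), base_epi, tolerance = 1e-9)
  }
})

test_that("all five parameters are invariant under joint rigid motion", {
  w <- default_wrist()
  lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  base <- c(
    uv = ulnar_variance_3d(lm$points$distal_ulnar_point,
                           lm$points$sigmoid_distal_point, w$frame),
    mru = mru_3d(lm, w$frame),
    epi = epicentre_3d(lm, w$frame),
    l = ulnocarpal_proximity(w$meshes$ulna, w$meshes$lunate)$distance,
    t = ulnocarpal_proximity(w$meshes$ulna, w$meshes$triquetrum)$distance
  )
  set.seed(5)
  for (k in 1:5) {
    tr <- rigid_transform(random_rotation(), rnorm(3, sd = 30))
    lm_t <- landmarks_transform(lm, tr)
    fr_t <- frame_transform(w$frame, tr)
    moved <- c(
      uv = ulnar_variance_3d(lm_t$points$distal_ulnar_point,
                             lm_t$points$sigmoid_distal_point, fr_t),
      mru = mru_3d(lm_t, fr_t),
      epi = epicentre_3d(lm_t, fr_t),
      l = ulnocarpal_proximity(mesh_transform(w$meshes$ulna, tr),
                               mesh_transform(w$meshes$lunate, tr))$distance,
      t = ulnocarpal_proximity(mesh_transform(w$meshes$ulna, tr),
                               mesh_transform(w$meshes$triquetrum,
                                              tr))$distance
    )
    expect_lt(max(abs(moved - base)), 1e-6)
  }
})

test_that("ulnocarpal proximity reports sites on the bone surfaces and
           warns on interpenetration", {
  w <- default_wrist()
  up <- ulnocarpal_proximity(w$meshes$ulna, w$meshes$lunate)
  expect_equal(up$distance, w$truth$ucp_l, tolerance = 1e-9)
  # sites realize the reported distance
  expect_equal(sqrt(sum((up$site_ulna - up$site_carpal)^2)), up$distance,
               tolerance = 1e-9)
  # translating the carpal along the closest-approach direction changes the
  # distance one-to-one
  dir <- (up$site_carpal - up$site_ulna) / up$distance
  lun2 <- triangle_mesh(sweep(w$meshes$lunate$vertices, 2, dir, "+"),
                        w$meshes$lunate$faces, "lunate")
  expect_equal(ulnocarpal_proximity(w$meshes$ulna, lun2)$distance,
               w$truth$ucp_l + 1, tolerance = 5e-3)
  # overlapping bones: zero with a warning
  inside <- triangle_mesh(
    sweep(scale(w$meshes$lunate$vertices, scale = FALSE), 2,
          colMeans(w$meshes$ulna$vertices[1:10, ]), "+"),
    w$meshes$lunate$faces, "lunate")
  expect_warning(res <- ulnocarpal_proximity(w$meshes$ulna, inside),
                 "interpenetrate")
  expect_identical(res$distance, 0)
  expect_error(ulnocarpal_proximity(w$meshes$ulna, w$meshes$capitate),
               "lunate or the triquetrum")
})
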