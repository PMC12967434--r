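test_that("all detectors recover the phantom's ground-truth landmarks", {
  w <- default_wrist()
  lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  expect_identical(lm$source, "auto")
  for (nm in names(lm$points)) {
    err <- sqrt(sum((lm$points[[nm]] - w$landmarks$points[[nm]])^2))
    expect_lt(err, 1.5)
  }
  # margins, corner, styloid and distal ulnar point are exact vertices
  for (nm in c("palmar_margin", "dorsal_margin", "palmar_radial_corner",
               "ulnar_styloid_tip", "distal_ulnar_point")) {
    expect_equal(lm$points[[nm]], w$landmarks$points[[nm]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # the head palmar point is refined sub-vertex; exact to fit precision
  expect_lt(sqrt(sum((lm$points$ulnar_head_palmar_point -
                        w$landmarks$points$ulnar_head_palmar_point)^2)),
            1e-6)
  # the notch distal point may sit one refined row proximal to the rim
  expect_lt(abs(lm$points$sigmoid_distal_point[3] -
                  w$landmarks$points$sigmoid_distal_point[3]), 0.1)
})

test_that("notch classification is a strict curvature threshold: values
           above it are kept, values below excluded", {
  w <- default_wrist()
  h <- mean_curvature(w$meshes$radius, mode = "longitudinal",
                      direction = w$frame$e_lon)
  reg <- sigmoid_notch_region(w$meshes$radius, w$frame)$region
  # every classified vertex exceeds 0.1/mm; e.g. a vertex at 0.11 would be
  # kept and one at 0.09 dropped
  expect_true(all(h[reg] > 0.1))
  # the facet's arc curvature is ~0.175/mm: a threshold just below keeps
  # the facet, a threshold above it empties the window
  reg_lo <- sigmoid_notch_region(w$meshes$radius, w$frame,
                                 curvature_threshold = 0.15)$region
  expect_true(length(reg_lo) > 0)
  expect_error(
    sigmoid_notch_region(w$meshes$radius, w$frame,
                         curvature_threshold = 0.35),
    "threshold")
})

test_that("styloid removal is idempotent: an ulna without a styloid gives
           the same distal point with cylinder radius 0", {
  w <- default_wrist()
  bald <- generate_wrist(wrist_params(styloid_length = 1e-9))
  p_full <- distal_ulnar_articular_point(w$meshes$ulna, w$frame,
                                         styloid_cylinder_radius = 4)
  p_bald <- suppressWarnings(
    distal_ulnar_articular_point(bald$meshes$ulna, bald$frame,
                                 styloid_cylinder_radius = 0))
  expect_equal(p_full, p_bald, tolerance = 1e-9)
  # a cylinder covering the whole head errors out
  expect_error(
    distal_ulnar_articular_point(w$meshes$ulna, w$frame,
                                 styloid_cylinder_radius = 1e3),
    "entire distal ulna")
})

test_that("landmark detection is equivariant under joint rigid motion and
           deterministic", {
  w <- default_wrist()
  lm0 <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  lm0b <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  for (nm in names(lm0$points)) {
    expect_identical(lm0$points[[nm]], lm0b$points[[nm]])
  }
  set.seed(3)
  for (k in 1:3) {
    tr <- rigid_transform(random_rotation(), rnorm(3, sd = 20))
    lm1 <- detect_landmarks(mesh_transform(w$meshes$radius, tr),
                            mesh_transform(w$meshes$ulna, tr),
                            frame_transform(w$frame, tr))
    for (nm in names(lm0$points)) {
      moved <- transform_points(tr, lm0$points[[nm]])
      expect_lt(sqrt(sum((lm1$points[[nm]] - moved)^2)), 1e-6)
    }
  }
})

test_that("auto-detected landmarks stay within 1.5 mm of ground truth over
           the generator's parameter ranges", {
  set.seed(99)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  worst <- 0
  for (k in 1:100) {
    wp <- wrist_params(
      uv3d = clip(rnorm(1, -0.4, 0.7), -1.8, 1.0),
      g_lunate = clip(rnorm(1, 3.2, 0.5), 1.8, 4.6),
      g_triquetrum = clip(rnorm(1, 6.9, 1.2), 4.5, 9.5),
      notch_width = clip(rnorm(1, 18, 0.8), 15.5, 19.0),
      head_radius = clip(rnorm(1, 10, 0.5), 9, 11),
      notch_depth = clip(rnorm(1, 2.2, 0.15), 1.9, 2.6),
      styloid_length = clip(rnorm(1, 5, 0.7), 3.5, 6.5)
    )
    w <- generate_wrist(wp)
    lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
    errs <- vapply(names(lm$points), function(nm) {
      sqrt(sum((lm$points[[nm]] - w$landmarks$points[[nm]])^2))
    }, numeric(1))
    worst <- max(worst, errs)
    expect_lt(max(errs), 1.5)
  }
  expect_lt(worst, 1.5)
})

test_that("provided landmarks bypass detection and mirror-normalized left
           wrists reproduce their right twin", {
  w <- default_wrist()
  lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame,
                         provided = w$landmarks)
  expect_identical(lm, w$landmarks)

  lw <- generate_wrist(wrist_params(side = "left"))
  norm <- frame_normalize_side(lw$frame, lw$meshes)
  lm_l <- detect_landmarks(norm$meshes$radius, norm$meshes$ulna, norm$frame)
  lm_r <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  for (nm in names(lm_r$points)) {
    expect_equal(lm_l$points[[nm]], lm_r$points[[nm]], tolerance = 1e-6)
  }
})

test_that("ulnar epicentre lies at the cap centre of a capped cylinder", {
  cyl <- mesh_cylinder(8, 100, center = c(0, 0, 0), n_phi = 24, n_z = 16)
  v <- cyl$vertices
  v[, 1] <- v[, 1] * 1.2 # avoid a perfectly degenerate eigen pair
  m <- triangle_mesh(v, cyl$faces)
  frame <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  epi <- ulnar_epicentre(m, frame)
  expect_equal(epi, c(0, 0, 50), tolerance = 1e-6)
})

test_that("landmark_set enforces its invariants", {
  w <- default_wrist()
  pts <- w$landmarks$points
  pts$notch_midpoint <- pts$notch_midpoint + c(0, 0.5, 0)
  expect_error(landmark_set(pts), "midpoint")
  pts <- w$landmarks$points
  pts$dorsal_margin <- pts$palmar_margin
  pts$notch_midpoint <- pts$palmar_margin
  expect_error(landmark_set(pts), "width")
  pts <- w$landmarks$points
  pts$ulnar_epicentre <- NULL
  expect_error(landmark_set(pts), "missing")
})
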