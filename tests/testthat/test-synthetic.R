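test_that("the phantom honours its prescriptions: watertight bones, exact
           gaps, prescribed ulnar variance, epicentre at the midpoint", {
  w <- default_wrist()
  for (m in w$meshes) expect_true(mesh_validate(m)$watertight)
  # prescribed gaps are realized exactly by construction
  expect_equal(min_distance(w$meshes$ulna, w$meshes$lunate)$distance,
               w$params$g_lunate, tolerance = 1e-9)
  expect_equal(min_distance(w$meshes$ulna, w$meshes$triquetrum)$distance,
               w$params$g_triquetrum, tolerance = 1e-9)
  # a different prescribed gap is honoured too
  w2 <- generate_wrist(wrist_params(g_lunate = 3.7))
  expect_equal(min_distance(w2$meshes$ulna, w2$meshes$lunate)$distance,
               3.7, tolerance = 0.05)
  # detector-measured uv within 0.1 mm of the prescription
  lm <- detect_landmarks(w$meshes$radius, w$meshes$ulna, w$frame)
  uv <- ulnar_variance_3d(lm$points$distal_ulnar_point,
                          lm$points$sigmoid_distal_point, w$frame)
  expect_lt(abs(uv - w$params$uv3d), 0.1)
  # neutral pose has the epicentre over the notch midpoint
  expect_equal(w$truth$epi3d, 0, tolerance = 1e-12)
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(wrist_params(notch_depth = 9.5), "deeper")
  expect_error(wrist_params(notch_width = 25), "wider")
  expect_error(wrist_params(g_lunate = -1), "gaps")
  expect_error(wrist_params(shaft_radius = 12), "smaller than head_radius")
  expect_error(wrist_params(notch_depth = 0.4, notch_extent = 9),
               "does not exceed")
})

test_that("left-side phantoms are the mirror twin of the right", {
  lw <- generate_wrist(wrist_params(side = "left"))
  rw <- default_wrist()
  expect_identical(lw$frame$side, "left")
  norm <- frame_normalize_side(lw$frame, lw$meshes)
  lm_l <- detect_landmarks(norm$meshes$radius, norm$meshes$ulna, norm$frame)
  uv_l <- ulnar_variance_3d(lm_l$points$distal_ulnar_point,
                            lm_l$points$sigmoid_distal_point, norm$frame)
  lm_r <- detect_landmarks(rw$meshes$radius, rw$meshes$ulna, rw$frame)
  uv_r <- ulnar_variance_3d(lm_r$points$distal_ulnar_point,
                            lm_r$points$sigmoid_distal_point, rw$frame)
  expect_equal(uv_l, uv_r, tolerance = 1e-6)
  expect_equal(mru_3d(lm_l, norm$frame), mru_3d(lm_r, rw$frame),
               tolerance = 1e-6)
  expect_equal(epicentre_3d(lm_l, norm$frame), epicentre_3d(lm_r, rw$frame),
               tolerance = 1e-6)
})

test_that("simulated motion carries exact analytic ground truth", {
  w <- default_wrist()
  # near-zero amplitude: constant series equal to the static values
  s0 <- simulate_motion(w, motion_params("FE", amplitude = c(-1e-9, 1e-9),
                                         n_frames = 3))
  expect_equal(s0$truth$uv3d_mm, rep(w$truth$uv3d, 3), tolerance = 1e-9)
  expect_equal(s0$truth$mru3d_pct, rep(w$truth$mru3d, 3), tolerance = 1e-6)
  expect_equal(s0$truth$epi3d_pct, rep(0, 3), tolerance = 1e-6)

  # PS with a linear dorso-palmar translation: epicentre range is the
  # closed form 100 * excursion / notch width
  t_max <- 1.4
  s <- simulate_motion(w, motion_params(
    "PS", n_frames = 9,
    dp_translation = function(th) t_max * th / 50,
    uv_drift = function(th) 0,
    approach_l = function(th) 0, approach_t = function(th) 0))
  rng <- motion_range(s$truth$epi3d_pct)
  expect_equal(rng, 100 * 2 * t_max / w$params$notch_width,
               tolerance = 1e-9)
  # the radioulnar-line response carries the cosine of the small obliquity
  # between the palmar-radial line and the radioulnar axis
  expect_lt(abs(motion_range(s$truth$mru3d_pct) -
                  100 * 2 * t_max / w$params$notch_width), 0.6)
  # wrist angle ground truth equals the commanded rotation
  expect_equal(s$truth$wrist_angle_deg, seq(-50, 50, length.out = 9),
               tolerance = 1e-9)
})

test_that("amplitudes outside the joint's feasible range are rejected", {
  expect_error(motion_params("RUD", amplitude = c(-80, 10)), "feasible")
  expect_error(motion_params("FE", amplitude = c(-40, 120)), "feasible")
  w <- default_wrist()
  expect_error(
    simulate_motion(w, motion_params(
      "RUD", approach_t = function(th) -th)), # would close the gap
    "gap")
})

test_that("degrade is seeded, reproducible and leaves ground truth alone", {
  w <- default_wrist()
  s <- simulate_motion(w, motion_params("RUD", n_frames = 4))
  d0 <- degrade(s, sigma = 0, seed = 3)
  # sigma = 0: targets are exactly the posed static vertices
  pose1 <- transform_points(s$poses[[2]]$radius, w$meshes$radius$vertices)
  expect_identical(d0$targets[[2]]$radius, pose1)
  d1 <- degrade(s, sigma = 0.25, seed = 3)
  d2 <- degrade(s, sigma = 0.25, seed = 3)
  expect_identical(d1$targets, d2$targets)
  d3 <- degrade(s, sigma = 0.25, seed = 4)
  expect_false(identical(d1$targets[[1]]$ulna, d3$targets[[1]]$ulna))
  expect_identical(d1$truth, s$truth)
  expect_error(degrade(s, decimation = 0.99), "100 vertices")
})
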