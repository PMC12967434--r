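test_that("principal axis recovers the symmetry axis of elongated shapes", {
  cyl <- mesh_cylinder(10, 100, n_phi = 36, n_z = 20)
  ax <- principal_longitudinal_axis(cyl)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  expect_equal(ax$point[1:2], c(0, 0), tolerance = 1e-6)

  # equivariance under a known rotation
  R <- rotation_about_axis(c(1, 2, 3), 37)
  rot <- mesh_transform(cyl, rigid_transform(R, c(5, -2, 1)))
  ax_r <- principal_longitudinal_axis(rot)
  expect_equal(abs(sum(ax_r$direction * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-6)

  # invariance to vertex reordering
  perm <- rev(seq_len(nrow(cyl$vertices)))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  shuffled <- triangle_mesh(cyl$vertices[perm, ],
                            matrix(inv[cyl$faces], ncol = 3))
  ax_s <- principal_longitudinal_axis(shuffled)
  expect_equal(abs(ax_s$direction[3]), 1, tolerance = 1e-6)
})

test_that("principal axis agrees with an independent eigen route and
           rejects near-isotropic meshes", {
  set.seed(42)
  v <- cbind(rnorm(400, sd = 9), rnorm(400, sd = 2.5), rnorm(400, sd = 1.5))
  R <- rotation_about_axis(c(1, -1, 2), 25)
  v <- v %*% t(R)
  m <- triangle_mesh(v, matrix(c(1, 2, 3), 1))
  ax <- principal_longitudinal_axis(m)
  # oracle: dominant right singular vector of the centred cloud (SVD route)
  sv <- svd(scale(v, scale = FALSE))$v[, 1]
  expect_equal(abs(sum(ax$direction * sv)), 1, tolerance = 1e-8)

  sph <- mesh_sphere(5, n_theta = 10, n_phi = 20)
  expect_error(principal_longitudinal_axis(sph), "not elongated")
})

test_that("mean curvature matches closed forms: sphere 1/r, plane 0,
           saddle 0 at apex, and scales as 1/r", {
  for (nt in c(16L, 32L)) { # two refinement levels
    s <- mesh_sphere(10, c(1, -2, 3), n_theta = nt, n_phi = 2L * nt)
    h <- mean_curvature(s)
    expect_lt(abs(median(h, na.rm = TRUE) - (-0.1)), 0.1 * 0.1)
  }
  s1 <- mesh_sphere(10, n_theta = 24, n_phi = 48)
  s2 <- mesh_sphere(20, n_theta = 24, n_phi = 48)
  expect_equal(median(mean_curvature(s2)) / median(mean_curvature(s1)), 0.5,
               tolerance = 0.02)

  x <- seq(-5, 5, by = 0.5)
  flat <- mesh_patch(x, x, matrix(0, length(x), length(x)))
  hf <- mean_curvature(flat)
  expect_lt(max(abs(hf), na.rm = TRUE), 1e-9)
  # boundary vertices are flagged as NA, not silently included
  expect_true(all(is.na(hf[attr(hf, "boundary")])))
  expect_gt(length(attr(hf, "boundary")), 0)

  # saddle z = (x^2 - y^2) / (2c): principal curvatures +-1/c, mean 0
  c_ <- 8
  saddle <- mesh_patch(x, x, outer(x, x, function(a, b) (a^2 - b^2) / (2 * c_)))
  hs <- mean_curvature(saddle)
  apex <- which(saddle$vertices[, 1] == 0 & saddle$vertices[, 2] == 0)
  expect_lt(abs(hs[apex]), 0.1 / c_)
})

test_that("concavity is positive: a carved trough exceeds the sphere's
           negative curvature convention", {
  s <- mesh_sphere(10, n_theta = 24, n_phi = 48)
  expect_lt(median(mean_curvature(s)), 0) # convex negative
  w <- default_wrist()
  notch <- sigmoid_notch_region(w$meshes$radius, w$frame)
  h <- mean_curvature(w$meshes$radius, mode = "longitudinal",
                      direction = w$frame$e_lon)
  expect_true(all(h[notch$region] > 0.1))
})

test_that("min_distance matches closed forms and is symmetric, non-negative
           and rigid-motion invariant", {
  a <- mesh_sphere(1, c(0, 0, 0), n_theta = 24, n_phi = 48)
  b <- mesh_sphere(1, c(4, 0, 0), n_theta = 24, n_phi = 48, axis = c(1, 0, 0))
  # pole vertex of b faces a; a's mesh is inscribed, so allow discretization
  d <- min_distance(a, b)
  expect_equal(d$distance, 2, tolerance = 1e-3)
  d_ba <- min_distance(b, a)
  expect_identical(d$distance, d_ba$distance)

  expect_identical(min_distance(a, a)$distance, 0)
  expect_true(min_distance(a, a)$intersecting)

  set.seed(7)
  m1 <- random_blob(1, c(0, 0, 0))
  m2 <- random_blob(2, c(3, 0.5, -0.5))
  d0 <- min_distance(m1, m2)$distance
  R <- random_rotation(); t <- rnorm(3)
  tr <- rigid_transform(R, t)
  d1 <- min_distance(mesh_transform(m1, tr), mesh_transform(m2, tr))$distance
  expect_lt(abs(d0 - d1), 1e-9)
  expect_gte(d0, 0)
})

test_that("min_distance equals the exhaustive brute-force oracle", {
  set.seed(11)
  for (k in 1:8) {
    m1 <- random_blob(100 + k, c(0, 0, 0), scale = runif(1, 0.5, 1.5))
    m2 <- random_blob(200 + k, c(runif(1, 1.5, 4), rnorm(1), rnorm(1)),
                      scale = runif(1, 0.5, 1.5))
    expect_equal(min_distance(m1, m2)$distance,
                 brute_force_min_distance(m1, m2), tolerance = 1e-9)
  }
})

test_that("rigid transforms compose, invert and validate", {
  R <- rotation_about_axis(c(0, 1, 1), 40)
  tr <- rigid_transform(R, c(1, 2, 3))
  inv <- transform_inverse(tr)
  comp <- transform_compose(inv, tr)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)

  p <- matrix(rnorm(30), 10, 3)
  expect_equal(transform_points(inv, transform_points(tr, p)), p,
               tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  # reflections are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "orthonormal|determinant")
})

test_that("ICP recovers exact poses and the identity, and rejects
           degenerate input", {
  cyl <- mesh_cylinder(8, 50, n_phi = 20, n_z = 10)
  v <- cyl$vertices
  v[, 1] <- v[, 1] * 1.25 # break rotational symmetry
  m <- triangle_mesh(v, cyl$faces)
  R <- rotation_about_axis(c(1, 2, 3), 10); t <- c(2, -1, 3)
  tgt <- mesh_transform(m, rigid_transform(R, t))
  tr <- rigid_register(m$vertices, tgt, tol = 1e-10)
  expect_lt(acos(pmin(1, (sum(diag(t(tr$rotation) %*% R)) - 1) / 2)), 1e-6)
  expect_lt(sqrt(sum((tr$translation - t)^2)), 1e-5)

  tr_id <- rigid_register(m$vertices, m, tol = 1e-10)
  expect_equal(tr_id$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tr_id$translation, c(0, 0, 0), tolerance = 1e-7)

  line <- cbind(seq(0, 1, length.out = 50), 0, 0)
  expect_error(rigid_register(line, m), "collinear")
})

test_that("re-registering an aligned pair is idempotent", {
  w <- default_wrist()
  src <- w$meshes$ulna$vertices
  src <- src[seq(1, nrow(src), by = 3), ]
  tr <- rigid_register(src, w$meshes$ulna, tol = 1e-9)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-7)
  expect_lt(sqrt(sum(tr$translation^2)), 1e-6)
})

test_that("frames validate orthonormality and handedness and mirror left
           wrists into the right-hand convention", {
  expect_error(anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0),
                                c(0, 0, 1)), "orthonormal")
  expect_error(anatomical_frame(c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                c(0, 0, 1)), "right-handed")

  f <- frame_from_axes(c(0, 0, 0), c(0, 0.1, 1), c(0, 1, 0), side = "right")
  B <- cbind(f$e_ru, f$e_pd, f$e_lon)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-12)
  expect_gt(det(B), 0)

  lw <- generate_wrist(wrist_params(side = "left"))
  norm <- frame_normalize_side(lw$frame, lw$meshes)
  expect_identical(norm$frame$side, "right")
  rw <- default_wrist()
  expect_equal(norm$meshes$radius$vertices, rw$meshes$radius$vertices,
               tolerance = 1e-9)
})
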