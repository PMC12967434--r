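# Independent scalar oracles used to cross-check the vectorized geometry.
# Deliberately written as straightforward per-pair loops with their own
# formulations (Eberly-style region tests), never calling the package's
# internal vectorized kernels.

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Closest point on triangle (rows of m) to p, via plane projection plus
# per-edge clamping.
oracle_point_tri <- function(p, m) {
  e0 <- m[2, ] - m[1, ]
  e1 <- m[3, ] - m[1, ]
  n <- c(e0[2] * e1[3] - e0[3] * e1[2],
         e0[3] * e1[1] - e0[1] * e1[3],
         e0[1] * e1[2] - e0[2] * e1[1])
  nn <- sum(n^2)
  best <- Inf
  if (nn > 0) {
    proj <- p - n * sum((p - m[1, ]) * n) / nn
    # barycentric via Cramer
    v2 <- proj - m[1, ]
    d00 <- sum(e0 * e0); d01 <- sum(e0 * e1); d11 <- sum(e1 * e1)
    d20 <- sum(v2 * e0); d21 <- sum(v2 * e1)
    den <- d00 * d11 - d01^2
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= 0 && v >= 0 && u + v <= 1) best <- sum((p - proj)^2)
  }
  for (ed in list(c(1, 2), c(2, 3), c(3, 1))) {
    a <- m[ed[1], ]; b <- m[ed[2], ]
    t <- sum((p - a) * (b - a)) / sum((b - a)^2)
    t <- min(1, max(0, t))
    q <- a + t * (b - a)
    best <- min(best, sum((p - q)^2))
  }
  best
}

oracle_seg_seg <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  b <- sum(d1 * d2); c <- sum(d1 * r); f <- sum(d2 * r)
  den <- a * e - b^2
  s <- if (den > 1e-300) min(1, max(0, (b * f - c * e) / den)) else 0
  t <- (b * s + f) / e
  if (t < 0) {
    t <- 0; s <- min(1, max(0, -c / a))
  } else if (t > 1) {
    t <- 1; s <- min(1, max(0, (b - c) / a))
  }
  sum((p1 + s * d1 - p2 - t * d2)^2)
}

oracle_seg_crosses_tri <- function(a, b, m) {
  e0 <- m[2, ] - m[1, ]; e1 <- m[3, ] - m[1, ]
  n <- c(e0[2] * e1[3] - e0[3] * e1[2],
         e0[3] * e1[1] - e0[1] * e1[3],
         e0[1] * e1[2] - e0[2] * e1[1])
  den <- sum(n * (b - a))
  if (abs(den) < 1e-14 * sqrt(sum(n^2)) * sqrt(sum((b - a)^2))) return(FALSE)
  t <- sum(n * (m[1, ] - a)) / den
  if (t < 0 || t > 1) return(FALSE)
  x <- a + t * (b - a)
  v2 <- x - m[1, ]
  d00 <- sum(e0 * e0); d01 <- sum(e0 * e1); d11 <- sum(e1 * e1)
  d20 <- sum(v2 * e0); d21 <- sum(v2 * e1)
  den2 <- d00 * d11 - d01^2
  u <- (d11 * d20 - d01 * d21) / den2
  v <- (d00 * d21 - d01 * d20) / den2
  u >= 0 && v >= 0 && u + v <= 1
}

oracle_tri_tri <- function(ta, tb) {
  for (i in 1:3) {
    ed <- list(c(1, 2), c(2, 3), c(3, 1))[[i]]
    if (oracle_seg_crosses_tri(ta[ed[1], ], ta[ed[2], ], tb)) return(0)
    if (oracle_seg_crosses_tri(tb[ed[1], ], tb[ed[2], ], ta)) return(0)
  }
  best <- Inf
  for (i in 1:3) best <- min(best, oracle_point_tri(ta[i, ], tb),
                             oracle_point_tri(tb[i, ], ta))
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  for (i in 1:3) for (j in 1:3) {
    best <- min(best, oracle_seg_seg(ta[edges[[i]][1], ], ta[edges[[i]][2], ],
                                     tb[edges[[j]][1], ], tb[edges[[j]][2], ]))
  }
  sqrt(best)
}

# Exhaustive all-pairs minimum distance between two meshes (no pruning).
brute_force_min_distance <- function(mesh_a, mesh_b) {
  va <- mesh_a$vertices; fa <- mesh_a$faces
  vb <- mesh_b$vertices; fb <- mesh_b$faces
  best <- Inf
  for (i in seq_len(nrow(fa))) {
    ta <- va[fa[i, ], , drop = FALSE]
    for (j in seq_len(nrow(fb))) {
      d <- oracle_tri_tri(ta, vb[fb[j, ], , drop = FALSE])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

# Small random blob mesh: unit sphere with seeded radial perturbation.
random_blob <- function(seed, center = c(0, 0, 0), scale = 1,
                        n_theta = 5L, n_phi = 8L) {
  set.seed(seed)
  m <- mesh_sphere(scale, center, n_theta = n_theta, n_phi = n_phi)
  r <- m$vertices - matrix(center, nrow(m$vertices), 3, byrow = TRUE)
  fac <- 1 + stats::runif(nrow(r), -0.3, 0.3)
  triangle_mesh(sweep(r * fac, 2, center, "+"), m$faces)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, 180))
}

# Default phantom shared by several test files (built once per run).
default_wrist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_wrist()
    cache
  }
})
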