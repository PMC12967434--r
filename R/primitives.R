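#' Primitive meshes
#'
#' Parametric watertight primitives used by the synthetic-wrist generator and
#' useful for closed-form checks: a UV sphere, a capped cylinder and an open
#' rectangular height-field patch.
#'
#' `mesh_sphere()` places a vertex exactly at each pole (+/- `axis`), which the
#' generator exploits to realize exact prescribed inter-bone gaps.
#'
#' @param radius Sphere/cylinder radius (mm).
#' @param center Length-3 centre (mm).
#' @param n_theta Number of latitude bands (sphere) or rings (cylinder cap).
#' @param n_phi Number of meridians.
#' @param axis Pole direction of the sphere parameterization (unit length not
#'   required).
#' @return A [triangle_mesh()].
#' @export
mesh_sphere <- function(radius = 1, center = c(0, 0, 0), n_theta = 16L,
                        n_phi = 32L, axis = c(0, 0, 1)) {
  B <- orthonormal_basis(axis)
  theta <- seq(0, pi, length.out = n_theta + 1L)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  # interior rings
  verts <- list(matrix(center + radius * B[, 3], 1))
  for (i in seq(2L, n_theta)) {
    st <- sin(theta[i]); ct <- cos(theta[i])
    ring <- t(center + radius * (B[, 1] %o% (st * cos(phi)) +
                                 B[, 2] %o% (st * sin(phi)) +
                                 B[, 3] %o% rep(ct, n_phi)))
    verts[[i]] <- ring
  }
  verts[[n_theta + 1L]] <- matrix(center - radius * B[, 3], 1)
  v <- do.call(rbind, verts)
  top <- 1L
  bot <- nrow(v)
  ring_start <- function(i) 2L + (i - 2L) * n_phi # i in 2..n_theta
  f <- list()
  # top cap
  r1 <- ring_start(2L)
  f[[length(f) + 1L]] <- cbind(top, r1 + (seq_len(n_phi) - 1L),
                               r1 + (seq_len(n_phi) %% n_phi))
  # bands
  if (n_theta > 2L) {
    for (i in seq(2L, n_theta - 1L)) {
      a <- ring_start(i) + (seq_len(n_phi) - 1L)
      a2 <- ring_start(i) + (seq_len(n_phi) %% n_phi)
      b <- ring_start(i + 1L) + (seq_len(n_phi) - 1L)
      b2 <- ring_start(i + 1L) + (seq_len(n_phi) %% n_phi)
      f[[length(f) + 1L]] <- cbind(a, b, b2)
      f[[length(f) + 1L]] <- cbind(a, b2, a2)
    }
  }
  # bottom cap
  rl <- ring_start(n_theta)
  f[[length(f) + 1L]] <- cbind(bot, rl + (seq_len(n_phi) %% n_phi),
                               rl + (seq_len(n_phi) - 1L))
  triangle_mesh(v, do.call(rbind, f))
}

#' @rdname mesh_sphere
#' @param length Cylinder length (mm), along `axis`, centred at `center`.
#' @param n_z Number of segments along the cylinder axis.
#' @export
mesh_cylinder <- function(radius = 1, length = 2, center = c(0, 0, 0),
                          axis = c(0, 0, 1), n_phi = 32L, n_z = 8L) {
  B <- orthonormal_basis(axis)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  z <- seq(-length / 2, length / 2, length.out = n_z + 1L)
  rings <- lapply(z, function(zz) {
    t(center + radius * (B[, 1] %o% cos(phi) + B[, 2] %o% sin(phi)) +
        B[, 3] %o% rep(zz, n_phi))
  })
  v <- do.call(rbind, rings)
  cap_bot <- nrow(v) + 1L
  cap_top <- nrow(v) + 2L
  v <- rbind(v, center + (-length / 2) * B[, 3], center + (length / 2) * B[, 3])
  f <- list()
  rs <- function(i) (i - 1L) * n_phi # ring i starts at rs(i)+1
  for (i in seq_len(n_z)) {
    a <- rs(i) + seq_len(n_phi)
    a2 <- rs(i) + (seq_len(n_phi) %% n_phi) + 1L
    b <- rs(i + 1L) + seq_len(n_phi)
    b2 <- rs(i + 1L) + (seq_len(n_phi) %% n_phi) + 1L
    f[[length(f) + 1L]] <- cbind(a, a2, b2)
    f[[length(f) + 1L]] <- cbind(a, b2, b)
  }
  a <- rs(1L) + seq_len(n_phi)
  a2 <- rs(1L) + (seq_len(n_phi) %% n_phi) + 1L
  f[[length(f) + 1L]] <- cbind(cap_bot, a2, a)
  b <- rs(n_z + 1L) + seq_len(n_phi)
  b2 <- rs(n_z + 1L) + (seq_len(n_phi) %% n_phi) + 1L
  f[[length(f) + 1L]] <- cbind(cap_top, b, b2)
  triangle_mesh(v, do.call(rbind, f))
}

#' @rdname mesh_sphere
#' @param x,y Strictly increasing grid coordinate vectors (mm).
#' @param z Matrix of heights, `length(x)` by `length(y)`.
#' @return For `mesh_patch()`, an open (non-watertight) height-field mesh with
#'   outward normals pointing towards +z.
#' @export
mesh_patch <- function(x, y, z) {
  nx <- length(x); ny <- length(y)
  stopifnot(all(dim(z) == c(nx, ny)))
  v <- cbind(rep(x, times = ny), rep(y, each = nx), as.numeric(z))
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(
    cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
    cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  )
  triangle_mesh(v, f)
}

# Right-handed orthonormal basis whose third column is along `axis`.
orthonormal_basis <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}
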