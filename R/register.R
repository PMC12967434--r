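#' Rigid iterative-closest-point registration
#'
#' Aligns a source point set to a target surface with a rigid transform, the
#' mesh-level surrogate for registering static-scan bone segmentations to
#' their dynamic positions. Point-to-plane ICP: at each iteration source
#' points are matched to their nearest target points, correspondences with
#' residuals above `reject_factor` times the median residual are rejected,
#' and the linearized point-to-plane least-squares problem is solved for an
#' incremental rotation and translation. Deterministic given inputs and
#' initialization; dynamic sequences should initialize each frame from the
#' previous frame's pose.
#'
#' @param source `n x 3` matrix of source points (mm), or a
#'   [triangle_mesh()] whose vertices are used.
#' @param target Target surface: a [triangle_mesh()] (vertices + outward
#'   vertex normals) or an `m x 3` point matrix (normals then estimated from
#'   local 10-point neighbourhoods).
#' @param init Initial [rigid_transform()] applied to the source
#'   (default identity).
#' @param max_iterations Iteration cap; non-convergence raises a warning and
#'   returns the best transform found.
#' @param tol Convergence threshold on the change in RMS residual (mm).
#' @param reject_factor Correspondences with residual above
#'   `reject_factor * median residual` are dropped (robustness to partial
#'   overlap); set `Inf` to keep all.
#' @return A [rigid_transform()] mapping source into target coordinates, with
#'   attributes `rms` (final RMS residual, mm), `iterations` and `converged`.
#' @export
rigid_register <- function(source, target, init = rigid_transform(),
                           max_iterations = 100L, tol = 1e-4,
                           reject_factor = 3) {
  src <- if (is_triangle_mesh(source)) source$vertices else as.matrix(source)
  if (nrow(src) < 3L) stop("source needs at least 3 points")
  if (is_triangle_mesh(target)) {
    tgt <- target$vertices
    tnorm <- vertex_normals(target)
  } else {
    tgt <- as.matrix(target)
    tnorm <- estimate_point_normals(tgt)
  }
  if (nrow(tgt) < 3L) stop("target needs at least 3 points")
  check_not_collinear(src)
  check_not_collinear(tgt)

  R <- init$rotation
  t <- init$translation
  tgt_sq <- rowSums(tgt^2)
  rms_prev <- Inf
  converged <- FALSE
  iters <- 0L
  rms <- NA_real_
  for (it in seq_len(max_iterations)) {
    iters <- it
    cur <- sweep(src %*% t(R), 2, t, "+")
    nn <- nearest_neighbours(cur, tgt, tgt_sq)
    q <- tgt[nn$index, , drop = FALSE]
    n <- tnorm[nn$index, , drop = FALSE]
    resid <- rowSums((cur - q) * n)
    keep <- rep(TRUE, length(resid))
    if (is.finite(reject_factor)) {
      med <- stats::median(nn$dist)
      keep <- nn$dist <= reject_factor * med + 1e-12
    }
    p <- cur[keep, , drop = FALSE]
    qk <- q[keep, , drop = FALSE]
    nk <- n[keep, , drop = FALSE]
    rk <- resid[keep]
    # linearized point-to-plane: minimize sum(( (p x n).w + n.v + n.(p-q) )^2)
    A <- cbind(row_cross(p, nk), nk)
    b <- -rk
    sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                    error = function(e) NULL)
    if (is.null(sol)) break
    w <- sol[1:3]; v <- sol[4:6]
    ang <- sqrt(sum(w^2))
    dR <- if (ang > 0) rotation_about_axis(w, ang * 180 / pi) else diag(3)
    R <- project_rotation(dR %*% R)
    t <- as.numeric(dR %*% t) + v
    rms <- sqrt(mean(rk^2))
    # the RMS residual plateaus at the noise floor, so convergence also
    # requires the incremental motion of the points to have died out
    step <- max(sqrt(rowSums((p %*% t(dR) - p)^2))) + sqrt(sum(v^2))
    if (abs(rms_prev - rms) < tol && step < 100 * tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  if (!converged) {
    warning(sprintf(
      "ICP did not converge in %d iterations (RMS %.4g mm); returning best transform",
      max_iterations, rms))
  }
  out <- rigid_transform(R, t)
  attr(out, "rms") <- rms
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}

# Nearest target point per source row (chunked brute force).
nearest_neighbours <- function(a, b, b_sq = rowSums(b^2)) {
  idx <- integer(nrow(a))
  d <- numeric(nrow(a))
  chunk <- max(1L, floor(4e6 / nrow(b)))
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    d2 <- cross_dist2(a[i0:i1, , drop = FALSE], b, b_sq)
    j <- max.col(-d2, ties.method = "first")
    idx[i0:i1] <- j
    d[i0:i1] <- sqrt(d2[cbind(seq_len(i1 - i0 + 1L), j)])
  }
  list(index = idx, dist = d)
}

# Normals of a raw point cloud from the smallest principal direction of the
# 10 nearest neighbours. Sign is arbitrary, which point-to-plane tolerates.
estimate_point_normals <- function(p, k = 10L) {
  k <- min(k, nrow(p) - 1L)
  n <- matrix(0, nrow(p), 3)
  chunk <- max(1L, floor(4e6 / nrow(p)))
  for (i0 in seq(1L, nrow(p), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(p))
    d2 <- cross_dist2(p[i0:i1, , drop = FALSE], p)
    for (ii in seq_len(i1 - i0 + 1L)) {
      row <- d2[ii, ]
      th <- sort(row, partial = k + 1L)[k + 1L]
      nb <- which(row <= th)[seq_len(k + 1L)]
      q <- p[nb, , drop = FALSE]
      cv <- crossprod(sweep(q, 2, colMeans(q)))
      n[i0 + ii - 1L, ] <- eigen(cv, symmetric = TRUE)$vectors[, 3]
    }
  }
  n
}

# Nearest rotation matrix (SVD projection), guards against drift.
project_rotation <- function(R) {
  s <- svd(R)
  out <- s$u %*% t(s$v)
  if (det(out) < 0) {
    s$u[, 3] <- -s$u[, 3]
    out <- s$u %*% t(s$v)
  }
  out
}

check_not_collinear <- function(p) {
  cv <- crossprod(sweep(p, 2, colMeans(p)))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9 * max(ev[1], 1e-300)) {
    stop("point set is (near-)collinear; rigid registration is degenerate")
  }
}
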