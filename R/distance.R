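#' Minimum distance between two bone surfaces
#'
#' Exact surface-to-surface (triangle-to-triangle) minimum distance in mm,
#' with the realizing closest point pair. Zero when the surfaces touch or
#' interpenetrate. Symmetric in its arguments. This is the primitive behind
#' ulnocarpal proximity (shortest 3-D distance from the ulna to the lunate or
#' triquetrum).
#'
#' Candidate triangle pairs are pruned with a centroid/circumradius bound
#' against a vertex-derived upper bound before the exact pairwise distance is
#' evaluated, so the result equals the exhaustive all-pairs minimum.
#'
#' @param mesh_a,mesh_b [triangle_mesh()] objects.
#' @return A list with `distance` (mm), `point_a`, `point_b` (closest points
#'   on the two surfaces) and `intersecting` (logical; `TRUE` when the
#'   surfaces cross, in which case `distance` is 0).
#' @export
min_distance <- function(mesh_a, mesh_b) {
  stopifnot(is_triangle_mesh(mesh_a), is_triangle_mesh(mesh_b))
  va <- mesh_a$vertices; fa <- mesh_a$faces
  vb <- mesh_b$vertices; fb <- mesh_b$faces

  # upper bound from nearest vertex pair (chunked)
  ub <- Inf
  chunk <- max(1L, floor(2e6 / nrow(vb)))
  for (i0 in seq(1L, nrow(va), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(va))
    d2 <- cross_dist2(va[i0:i1, , drop = FALSE], vb)
    ub <- min(ub, sqrt(min(d2)))
  }

  # pre-filter: triangles farther from the other mesh's bounding box than
  # the vertex upper bound cannot contain the minimum
  fa_keep <- which(tri_box_distance(va, fa, vb) <= ub + 1e-12)
  fb_keep <- which(tri_box_distance(vb, fb, va) <= ub + 1e-12)
  fa <- fa[fa_keep, , drop = FALSE]
  fb <- fb[fb_keep, , drop = FALSE]

  ca <- tri_centroids(va, fa); cb <- tri_centroids(vb, fb)
  ra <- tri_circumradius(va, fa, ca); rb <- tri_circumradius(vb, fb, cb)

  best <- list(distance = Inf, point_a = NULL, point_b = NULL,
               intersecting = FALSE)
  chunk <- max(1L, floor(2e6 / nrow(fb)))
  for (i0 in seq(1L, nrow(fa), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(fa))
    idx_a <- i0:i1
    d <- sqrt(cross_dist2(ca[idx_a, , drop = FALSE], cb))
    lower <- d - ra[idx_a] - rep(rb, each = length(idx_a))
    keep <- which(lower <= min(ub, best$distance) + 1e-12)
    if (!length(keep)) next
    ia <- idx_a[(keep - 1L) %% length(idx_a) + 1L]
    ib <- (keep - 1L) %/% length(idx_a) + 1L
    res <- tri_tri_distance(
      va[fa[ia, 1], , drop = FALSE], va[fa[ia, 2], , drop = FALSE],
      va[fa[ia, 3], , drop = FALSE],
      vb[fb[ib, 1], , drop = FALSE], vb[fb[ib, 2], , drop = FALSE],
      vb[fb[ib, 3], , drop = FALSE]
    )
    k <- which.min(res$dist)
    if (res$dist[k] < best$distance) {
      best$distance <- res$dist[k]
      best$point_a <- res$pa[k, ]
      best$point_b <- res$pb[k, ]
      best$intersecting <- res$dist[k] == 0 && any(res$intersect)
    }
    if (any(res$intersect)) best$intersecting <- TRUE
  }
  best
}

cross_dist2 <- function(a, b, b_sq = rowSums(b^2)) {
  # squared distances between rows of a (k x 3) and rows of b (n x 3)
  d2 <- -2 * tcrossprod(a, b)
  d2 <- d2 + rowSums(a^2)          # recycles down columns
  d2 <- sweep(d2, 2, b_sq, "+")
  d2[d2 < 0] <- 0
  d2
}

# Distance from each triangle's AABB to the other point set's AABB.
tri_box_distance <- function(v, f, other) {
  lo <- apply(other, 2, min); hi <- apply(other, 2, max)
  d2 <- numeric(nrow(f))
  for (k in 1:3) {
    ck <- cbind(v[f[, 1], k], v[f[, 2], k], v[f[, 3], k])
    tlo <- pmin(ck[, 1], ck[, 2], ck[, 3])
    thi <- pmax(ck[, 1], ck[, 2], ck[, 3])
    gap <- pmax(0, pmax(lo[k] - thi, tlo - hi[k]))
    d2 <- d2 + gap^2
  }
  sqrt(d2)
}

tri_centroids <- function(v, f) {
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

tri_circumradius <- function(v, f, ctr) {
  sqrt(pmax(
    rowSums((v[f[, 1], , drop = FALSE] - ctr)^2),
    rowSums((v[f[, 2], , drop = FALSE] - ctr)^2),
    rowSums((v[f[, 3], , drop = FALSE] - ctr)^2)
  ))
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Closest points between point rows P and segment rows (S0, S1).
point_segment_closest <- function(p, s0, s1) {
  d <- s1 - s0
  len2 <- rowSums(d^2)
  len2[len2 < 1e-300] <- 1e-300
  t <- rowSums((p - s0) * d) / len2
  t <- pmin(1, pmax(0, t))
  s0 + d * t
}

# Closest points on triangles (a, b, c) to point rows p.
point_triangle_closest <- function(p, a, b, c) {
  v0 <- b - a; v1 <- c - a
  n <- row_cross(v0, v1)
  nn <- rowSums(n^2)
  nn[nn < 1e-300] <- 1e-300
  w <- p - a
  proj <- p - n * (rowSums(w * n) / nn)
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  v2 <- proj - a
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01^2
  den[abs(den) < 1e-300] <- 1e-300
  u <- (d11 * d20 - d01 * d21) / den
  vv <- (d00 * d21 - d01 * d20) / den
  inside <- u >= 0 & vv >= 0 & (u + vv) <= 1
  out <- proj
  if (any(!inside)) {
    io <- which(!inside)
    cand1 <- point_segment_closest(p[io, , drop = FALSE],
                                   a[io, , drop = FALSE], b[io, , drop = FALSE])
    cand2 <- point_segment_closest(p[io, , drop = FALSE],
                                   b[io, , drop = FALSE], c[io, , drop = FALSE])
    cand3 <- point_segment_closest(p[io, , drop = FALSE],
                                   c[io, , drop = FALSE], a[io, , drop = FALSE])
    d1 <- rowSums((p[io, , drop = FALSE] - cand1)^2)
    d2 <- rowSums((p[io, , drop = FALSE] - cand2)^2)
    d3 <- rowSums((p[io, , drop = FALSE] - cand3)^2)
    pick <- max.col(-cbind(d1, d2, d3), ties.method = "first")
    res <- cand1
    res[pick == 2, ] <- cand2[pick == 2, , drop = FALSE]
    res[pick == 3, ] <- cand3[pick == 3, , drop = FALSE]
    out[io, ] <- res
  }
  out
}

# Closest points between segment rows (p1, q1) and (p2, q2). Lumelsky clamp.
segment_segment_closest <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2)
  b <- rowSums(d1 * d2); c <- rowSums(d1 * r); f <- rowSums(d2 * r)
  a_ <- pmax(a, 1e-300); e_ <- pmax(e, 1e-300)
  den <- a_ * e_ - b^2
  s <- ifelse(den > 1e-300, pmin(1, pmax(0, (b * f - c * e_) / den)), 0)
  t <- (b * s + f) / e_
  tc <- pmin(1, pmax(0, t))
  # where t was clamped, recompute s
  redo <- t != tc
  s2 <- pmin(1, pmax(0, (b * tc - c) / a_))
  s <- ifelse(redo, s2, s)
  ca <- p1 + d1 * s
  cb <- p2 + d2 * tc
  list(pa = ca, pb = cb, dist2 = rowSums((ca - cb)^2))
}

# Do segment rows (e0, e1) cross triangle rows (a, b, c)?
segment_triangle_intersects <- function(e0, e1, a, b, c) {
  dir <- e1 - e0
  n <- row_cross(b - a, c - a)
  den <- rowSums(n * dir)
  ok <- abs(den) > 1e-12 * sqrt(rowSums(n^2)) * sqrt(rowSums(dir^2))
  den[!ok] <- 1
  t <- rowSums(n * (a - e0)) / den
  valid <- ok & t >= 0 & t <= 1
  x <- e0 + dir * t
  v0 <- b - a; v1 <- c - a; v2 <- x - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  dd <- d00 * d11 - d01^2
  dd[abs(dd) < 1e-300] <- 1e-300
  u <- (d11 * d20 - d01 * d21) / dd
  v <- (d00 * d21 - d01 * d20) / dd
  list(hit = valid & u >= 0 & v >= 0 & (u + v) <= 1, point = x)
}

# Exact distance between triangle rows (a1,a2,a3) and (b1,b2,b3):
# minimum over 9 edge-edge and 6 vertex-triangle candidates, 0 on crossing.
tri_tri_distance <- function(a1, a2, a3, b1, b2, b3) {
  k <- nrow(a1)
  best <- rep(Inf, k)
  pa <- matrix(0, k, 3); pb <- matrix(0, k, 3)
  upd <- function(d2, ca, cb) {
    better <- d2 < best
    if (any(better)) {
      best[better] <<- d2[better]
      pa[better, ] <<- ca[better, , drop = FALSE]
      pb[better, ] <<- cb[better, , drop = FALSE]
    }
  }
  ea <- list(list(a1, a2), list(a2, a3), list(a3, a1))
  eb <- list(list(b1, b2), list(b2, b3), list(b3, b1))
  for (i in 1:3) for (j in 1:3) {
    ss <- segment_segment_closest(ea[[i]][[1]], ea[[i]][[2]],
                                  eb[[j]][[1]], eb[[j]][[2]])
    upd(ss$dist2, ss$pa, ss$pb)
  }
  for (p in list(a1, a2, a3)) {
    cp <- point_triangle_closest(p, b1, b2, b3)
    upd(rowSums((p - cp)^2), p, cp)
  }
  for (p in list(b1, b2, b3)) {
    cp <- point_triangle_closest(p, a1, a2, a3)
    upd(rowSums((p - cp)^2), cp, p)
  }
  inter <- rep(FALSE, k)
  for (i in 1:3) {
    hit <- segment_triangle_intersects(ea[[i]][[1]], ea[[i]][[2]], b1, b2, b3)
    if (any(hit$hit)) {
      inter <- inter | hit$hit
      best[hit$hit] <- 0
      pa[hit$hit, ] <- hit$point[hit$hit, , drop = FALSE]
      pb[hit$hit, ] <- hit$point[hit$hit, , drop = FALSE]
    }
    hit <- segment_triangle_intersects(eb[[i]][[1]], eb[[i]][[2]], a1, a2, a3)
    if (any(hit$hit)) {
      inter <- inter | hit$hit
      best[hit$hit] <- 0
      pa[hit$hit, ] <- hit$point[hit$hit, , drop = FALSE]
      pb[hit$hit, ] <- hit$point[hit$hit, , drop = FALSE]
    }
  }
  list(dist = sqrt(best), pa = pa, pb = pb, intersect = inter)
}
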