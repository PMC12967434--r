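#' Read and write surface meshes (STL and PLY)
#'
#' Minimal readers/writers for the two interchange formats used for
#' segmented bone surfaces, preserving millimetre coordinates. STL is
#' detected as binary or ASCII automatically on read; `mesh_write_stl()`
#' writes binary by default (`ascii = TRUE` for ASCII). STL stores loose
#' triangles, so vertices are merged exactly on read. PLY support covers
#' ASCII files with `vertex` (x, y, z) and `face` elements.
#'
#' @param path File path.
#' @param bone_label Optional bone label attached to the mesh on read.
#' @param mesh A [triangle_mesh()].
#' @param ascii Write ASCII STL instead of binary.
#' @return Readers return a [triangle_mesh()]; writers return `path`
#'   invisibly.
#' @export
mesh_read_stl <- function(path, bone_label = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  if (!is.na(n_tri) && sz == 84 + 50 * n_tri) {
    tri <- matrix(0, n_tri, 9)
    for (i in seq_len(n_tri)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      tri[i, ] <- vals[4:12]
    }
  } else {
    close(con)
    on.exit()
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }, numeric(3)))
    if (nrow(nums) %% 3 != 0) stop("malformed ASCII STL: ", path)
    tri <- matrix(as.numeric(t(nums)), ncol = 9, byrow = TRUE)
  }
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  ord <- c(t(matrix(seq_len(3 * nrow(tri)), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]  # v1,v2,v3 per triangle, in order
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  triangle_mesh(verts[uk, , drop = FALSE],
                matrix(idx, ncol = 3, byrow = TRUE), bone_label)
}

#' @rdname mesh_read_stl
#' @export
mesh_write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    lines <- c(
      "solid mesh",
      unlist(lapply(seq_len(nrow(f)), function(i) {
        p <- v[f[i, ], , drop = FALSE]
        c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
          "    outer loop",
          sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
          "    endloop",
          "  endfacet")
      })),
      "endsolid mesh"
    )
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(n[i, ], t(v[f[i, ], , drop = FALSE])), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  }
  invisible(path)
}

#' @rdname mesh_read_stl
#' @export
mesh_read_ply <- function(path, bone_label = NA_character_) {
  txt <- readLines(path, warn = FALSE)
  end_hdr <- which(txt == "end_header")[1]
  if (is.na(end_hdr)) stop("not a PLY file: ", path)
  hdr <- txt[seq_len(end_hdr)]
  if (!grepl("ascii", hdr[2])) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", hdr,
                                                value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", hdr,
                                              value = TRUE)[1]))
  body <- txt[(end_hdr + 1):length(txt)]
  vl <- body[seq_len(nv)]
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  fl <- body[nv + seq_len(nf)]
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop("only triangle faces are supported")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  triangle_mesh(v, f, bone_label)
}

#' @rdname mesh_read_stl
#' @export
mesh_write_ply <- function(mesh, path) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header",
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract per-bone surfaces from a labeled volume
#'
#' Converts an integer label volume (e.g. a NIfTI segmentation with one
#' label per bone) into per-label triangle meshes by isosurfacing the binary
#' mask of each label at level 0.5 with marching tetrahedra (each voxel cell
#' split into six tetrahedra; watertight per label). Vertex coordinates are
#' scaled by the voxel size so meshes are in mm.
#'
#' @param volume 3-D integer array, or a path to a NIfTI file (read with
#'   the RNifti package; its header supplies the voxel size).
#' @param voxel_size Length-3 voxel spacing in mm (ignored when a NIfTI
#'   header provides it).
#' @param labels Integer labels to extract (default: all non-zero labels).
#' @param label_names Optional character vector naming each label's bone
#'   (same length as `labels`), attached as `bone_label`.
#' @return Named list of [triangle_mesh()] objects (names are the labels or
#'   `label_names`).
#' @export
label_volume_to_meshes <- function(volume, voxel_size = c(1, 1, 1),
                                   labels = NULL, label_names = NULL) {
  if (is.character(volume)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI files requires the RNifti package")
    }
    img <- RNifti::readNifti(volume)
    voxel_size <- RNifti::pixdim(img)[1:3]
    volume <- as.array(img)
  }
  stopifnot(length(dim(volume)) == 3)
  if (is.null(labels)) {
    labels <- sort(setdiff(unique(as.integer(volume)), 0L))
  }
  if (!is.null(label_names)) stopifnot(length(label_names) == length(labels))
  out <- lapply(seq_along(labels), function(k) {
    mask <- array(as.numeric(volume == labels[k]), dim(volume))
    m <- marching_tetrahedra(mask, level = 0.5, spacing = voxel_size)
    if (!is.null(label_names)) m$bone_label <- label_names[k]
    m
  })
  names(out) <- if (is.null(label_names)) as.character(labels) else label_names
  out
}

# Marching tetrahedra isosurface of a scalar 3-D array at `level`.
# Each cube cell is split into 6 tetrahedra sharing the main diagonal, so
# adjacent cells agree on shared faces and the surface is watertight for
# masks not touching the array border.
marching_tetrahedra <- function(vol, level = 0.5, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # cell corner offsets (0/1) indexed 1..8
  corner <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  # six tetrahedra around the diagonal corner1-corner7
  tets <- rbind(
    c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
  )
  # active cells: those with both signs among their 8 corners
  cell_idx <- which(vol[-nx, -ny, -nz] > -Inf) # all cells, then filter
  ci <- arrayInd(cell_idx, d - 1L)
  above <- matrix(FALSE, nrow(ci), 8)
  for (k in 1:8) {
    above[, k] <- vol[cbind(ci[, 1] + corner[k, 1], ci[, 2] + corner[k, 2],
                            ci[, 3] + corner[k, 3])] > level
  }
  nab <- rowSums(above)
  act <- which(nab > 0 & nab < 8)
  tris <- list()
  for (a in act) {
    base <- ci[a, ]
    vals <- vol[cbind(base[1] + corner[, 1], base[2] + corner[, 2],
                      base[3] + corner[, 3])]
    pts <- sweep(corner, 2, base - 1L, "+") # 0-based grid coords + base
    for (t_ in seq_len(6)) {
      id <- tets[t_, ]
      tv <- vals[id]
      inside <- tv > level
      ns <- sum(inside)
      if (ns == 0 || ns == 4) next
      p <- pts[id, , drop = FALSE]
      interp <- function(i, j) {
        w <- (level - tv[i]) / (tv[j] - tv[i])
        p[i, ] + w * (p[j, ] - p[i, ])
      }
      io <- which(inside); oo <- which(!inside)
      inner_ref <- colMeans(p[io, , drop = FALSE])
      if (ns == 1) {
        tri <- rbind(interp(io, oo[1]), interp(io, oo[2]), interp(io, oo[3]))
        tris[[length(tris) + 1L]] <- orient_tri(tri, inner_ref)
      } else if (ns == 3) {
        tri <- rbind(interp(io[1], oo), interp(io[2], oo), interp(io[3], oo))
        tris[[length(tris) + 1L]] <- orient_tri(tri, inner_ref)
      } else {
        q <- rbind(interp(io[1], oo[1]), interp(io[1], oo[2]),
                   interp(io[2], oo[2]), interp(io[2], oo[1]))
        tris[[length(tris) + 1L]] <- orient_tri(q[c(1, 2, 3), ], inner_ref)
        tris[[length(tris) + 1L]] <- orient_tri(q[c(1, 3, 4), ], inner_ref)
      }
    }
  }
  if (!length(tris)) stop("no isosurface at this level")
  verts <- do.call(rbind, tris)
  key <- paste(round(verts[, 1], 9), round(verts[, 2], 9),
               round(verts[, 3], 9))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  v <- verts[uk, , drop = FALSE]
  v <- sweep(v, 2, spacing, "*")
  triangle_mesh(v, matrix(idx, ncol = 3, byrow = TRUE))
}

# Orient a triangle so its normal points away from `inside_pt` (outward).
orient_tri <- function(tri, inside_pt) {
  n <- c(
    (tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
      (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
    (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
      (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
    (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
      (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
  )
  outward <- sum(n * (colMeans(tri) - inside_pt))
  if (outward < 0) tri[c(1, 3, 2), ] else tri
}
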