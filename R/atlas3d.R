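#' Stack registered section masks into a 3D volume
#'
#' Sections are stacked along z in physical order with the given voxel
#' spacing (z defaults to the 10-micrometer section thickness). An optional
#' in-plane downsampling factor (block-OR for masks) is applied and recorded.
#'
#' @param masks ordered list of `BinaryMask` (or numeric/logical matrices) of
#'   identical shape, one per section.
#' @param spacing named numeric `c(z, y, x)` voxel spacing in micrometers.
#' @param downsample integer in-plane downsampling factor (>= 1).
#' @return object of class `Volume`: list with `voxels` (array
#'   rows x cols x sections), `spacing`, `downsample`.
#' @export
assemble_volume <- function(masks, spacing = c(z = 10, y = 1, x = 1),
                            downsample = 1L) {
  if (!length(masks)) {
    return(structure(list(voxels = array(FALSE, c(0, 0, 0)),
                          spacing = spacing, downsample = downsample),
                     class = "Volume"))
  }
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  grids <- lapply(masks, function(m) {
    if (inherits(m, "BinaryMask")) m$grid else m != 0
  })
  shp <- vapply(grids, function(g) paste(dim(g), collapse = "x"), "")
  if (length(unique(shp)) != 1L) stop("section shapes differ")
  if (downsample > 1L) {
    k <- as.integer(downsample)
    grids <- lapply(grids, function(g) {
      nr <- floor(nrow(g) / k) * k; nc <- floor(ncol(g) / k) * k
      g <- g[seq_len(nr), seq_len(nc), drop = FALSE]
      # block-OR: any foreground voxel in a k x k block marks the block
      blk <- matrix(FALSE, nr / k, nc / k)
      for (i in seq_len(k)) for (j in seq_len(k))
        blk <- blk | g[seq(i, nr, by = k), seq(j, nc, by = k), drop = FALSE]
      blk
    })
    spacing[c("y", "x")] <- spacing[c("y", "x")] * k
  }
  vox <- array(FALSE, c(dim(grids[[1]]), length(grids)))
  for (s in seq_along(grids)) vox[, , s] <- grids[[s]]
  structure(list(voxels = vox, spacing = spacing,
                 downsample = as.integer(downsample)),
            class = "Volume")
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volume %d x %d x %d voxels, spacing z=%g y=%g x=%g um, %d fg\n",
              d[1], d[2], d[3], x$spacing["z"], x$spacing["y"], x$spacing["x"],
              sum(x$voxels)))
  invisible(x)
}

# 6-tetrahedra decomposition of the unit cube around the 0-6 diagonal.
# Corner numbering: bit 0 = x, bit 1 = y, bit 2 = z offsets.
CUBE_CORNERS <- cbind(x = c(0, 1, 1, 0, 0, 1, 1, 0),
                      y = c(0, 0, 1, 1, 0, 0, 1, 1),
                      z = c(0, 0, 0, 0, 1, 1, 1, 1))
CUBE_TETS <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                   c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

#' Extract an isosurface mesh from a volume
#'
#' Marching-tetrahedra isosurface: each voxel cube is split into six
#' tetrahedra sharing the main diagonal (which makes neighboring cubes agree
#' on the face diagonals, so the mesh is crack-free and watertight for
#' zero-padded binary volumes), and each tetrahedron crossed by the iso level
#' contributes one or two triangles with vertices placed by linear
#' interpolation along the crossing edges. Vertices are scaled by the voxel
#' spacing into micrometer coordinates; triangle windings are oriented so
#' normals point out of the foreground.
#'
#' @param volume `Volume` (boolean or scalar voxels) with at least one
#'   foreground/above-level voxel.
#' @param level iso level; 0.5 (default) for boolean volumes.
#' @return object of class `Mesh`: list with `vertices` (3T x 3 matrix of
#'   x, y, z in micrometers, consecutive triples = triangles) and `normals`
#'   (T x 3 unit normals).
#' @export
volume_to_mesh <- function(volume, level = 0.5) {
  stopifnot(inherits(volume, "Volume"))
  v <- volume$voxels * 1
  if (!length(v) || max(v) < level) stop("empty volume: nothing above level")
  d <- dim(v)
  # zero padding closes the surface at the volume boundary
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  sx <- volume$spacing[["x"]]; sy <- volume$spacing[["y"]]
  sz <- volume$spacing[["z"]]

  # cube origin voxel centers in padded index space; voxel (r,c,s) of the
  # original volume has center ((c-0.5)sx, (r-0.5)sy, (s-0.5)sz)
  dims <- dim(p)
  idx <- which(p >= level, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty volume: nothing above level")
  # candidate cubes: those whose corner block contains any foreground corner
  cand <- unique(do.call(rbind, lapply(list(c(0, 0, 0), c(-1, 0, 0), c(0, -1, 0),
                                            c(0, 0, -1), c(-1, -1, 0), c(-1, 0, -1),
                                            c(0, -1, -1), c(-1, -1, -1)),
                                       function(o) sweep(idx, 2, -o))))
  keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] - 1 &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] - 1 &
          cand[, 3] >= 1 & cand[, 3] <= dims[3] - 1
  cand <- cand[keep, , drop = FALSE]

  tri <- list()
  interp <- function(pa, pb, fa, fb) pa + (level - fa) / (fb - fa) * (pb - pa)
  for (k in seq_len(nrow(cand))) {
    r0 <- cand[k, 1]; c0 <- cand[k, 2]; s0 <- cand[k, 3]
    f <- p[cbind(r0 + CUBE_CORNERS[, "y"], c0 + CUBE_CORNERS[, "x"],
                 s0 + CUBE_CORNERS[, "z"])]
    if (all(f >= level) || all(f < level)) next
    # corner positions in physical um (padded index -> original voxel center)
    pos <- cbind(x = (c0 + CUBE_CORNERS[, "x"] - 1.5) * sx,
                 y = (r0 + CUBE_CORNERS[, "y"] - 1.5) * sy,
                 z = (s0 + CUBE_CORNERS[, "z"] - 1.5) * sz)
    for (t in seq_len(nrow(CUBE_TETS))) {
      tc <- CUBE_TETS[t, ]
      ft <- f[tc]
      inside <- ft >= level
      ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      pt <- pos[tc, , drop = FALSE]
      if (ni == 1L || ni == 3L) {
        apex <- if (ni == 1L) which(inside) else which(!inside)
        others <- setdiff(1:4, apex)
        verts <- t(vapply(others, function(o)
          interp(pt[apex, ], pt[o, ], ft[apex], ft[o]), numeric(3)))
        inside_pt <- if (ni == 1L) pt[apex, ]
                     else colMeans(pt[others, , drop = FALSE])
        tri[[length(tri) + 1L]] <- orient_triangle(verts, inside_pt)
      } else {
        ins <- which(inside); outs <- which(!inside)
        eAC <- interp(pt[ins[1], ], pt[outs[1], ], ft[ins[1]], ft[outs[1]])
        eAD <- interp(pt[ins[1], ], pt[outs[2], ], ft[ins[1]], ft[outs[2]])
        eBC <- interp(pt[ins[2], ], pt[outs[1], ], ft[ins[2]], ft[outs[1]])
        eBD <- interp(pt[ins[2], ], pt[outs[2], ], ft[ins[2]], ft[outs[2]])
        inside_pt <- colMeans(pt[ins, , drop = FALSE])
        tri[[length(tri) + 1L]] <- orient_triangle(rbind(eAC, eAD, eBD),
                                                   inside_pt)
        tri[[length(tri) + 1L]] <- orient_triangle(rbind(eAC, eBD, eBC),
                                                   inside_pt)
      }
    }
  }
  if (!length(tri)) stop("no surface crossed the iso level")
  vertices <- do.call(rbind, tri)
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, normals = facet_normals(vertices)),
            class = "Mesh")
}

# flip the triangle so its normal points away from the inside reference point
orient_triangle <- function(verts, inside_pt) {
  n <- cross3(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ])
  if (sum(n * (colMeans(verts) - inside_pt)) < 0) verts[c(1, 3, 2), ]
  else verts
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

facet_normals <- function(vertices) {
  nt <- nrow(vertices) / 3
  n <- matrix(0, nt, 3)
  for (i in seq_len(nt)) {
    v <- vertices[(3 * i - 2):(3 * i), , drop = FALSE]
    cr <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    len <- sqrt(sum(cr^2))
    n[i, ] <- if (len > 0) cr / len else c(0, 0, 1)
  }
  n
}

#' @export
print.Mesh <- function(x, ...) {
  cat(sprintf("Mesh: %d triangles, bbox x [%.3g, %.3g] y [%.3g, %.3g] z [%.3g, %.3g] um\n",
              nrow(x$vertices) / 3,
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2]),
              min(x$vertices[, 3]), max(x$vertices[, 3])))
  invisible(x)
}

# deduplicate mesh vertices (rounded to tol) and return triangle->vertex ids
mesh_topology <- function(mesh, tol = 1e-6) {
  v <- round(mesh$vertices / tol) * tol
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  uid <- match(key, unique(key))
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(n_vertices = length(unique(uid)), faces = faces)
}

#' Topological summaries of a triangle mesh
#'
#' `mesh_euler_characteristic` returns V - E + F on the deduplicated mesh
#' (2 for a watertight genus-0 surface). `mesh_component_count` counts
#' connected components of triangles joined by shared edges (the mesh
#' processing convention: surfaces touching at a single vertex are separate
#' components); for isosurfaces of binary volumes this equals the number of
#' face-adjacent (6-connected) foreground voxel components.
#' `mesh_surface_area` is the total triangle area.
#'
#' @param mesh `Mesh`.
#' @return scalar.
#' @export
mesh_euler_characteristic <- function(mesh) {
  topo <- mesh_topology(mesh)
  f <- topo$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  edges <- unique(t(apply(edges, 1, sort)))
  topo$n_vertices - nrow(edges) + nrow(f)
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_component_count <- function(mesh) {
  topo <- mesh_topology(mesh)
  nt <- nrow(topo$faces)
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # map each undirected edge to the triangles that carry it
  f <- topo$faces
  ek <- c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
          paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
          paste(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3])))
  tri_id <- rep(seq_len(nt), 3)
  for (grp in split(tri_id, ek)) {
    if (length(grp) < 2) next
    a <- find(grp[1])
    for (t in grp[-1]) parent[find(t)] <- a
  }
  length(unique(vapply(seq_len(nt), find, 0L)))
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_surface_area <- function(mesh) {
  nt <- nrow(mesh$vertices) / 3
  a <- 0
  for (i in seq_len(nt)) {
    v <- mesh$vertices[(3 * i - 2):(3 * i), , drop = FALSE]
    a <- a + sqrt(sum(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])^2)) / 2
  }
  a
}

#' Write a mesh as an STL file
#'
#' Binary STL (80-byte header, 4-byte little-endian triangle count, 50 bytes
#' per facet) by default, or ASCII STL. Round-trip safe with [read_stl()].
#'
#' @param mesh `Mesh` with at least one triangle.
#' @param path output path.
#' @param mode `"binary"` or `"ascii"`.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii"),
                      name = "pepatlas") {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "Mesh"))
  nt <- nrow(mesh$vertices) / 3
  if (nt < 1) stop("mesh has no triangles")
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header <- charToRaw(sprintf("%-80s", name))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    for (i in seq_len(nt)) {
      writeBin(as.numeric(mesh$normals[i, ]), con, size = 4, endian = "little")
      v <- t(mesh$vertices[(3 * i - 2):(3 * i), , drop = FALSE])
      writeBin(as.numeric(v), con, size = 4, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    }
  } else {
    lines <- c(sprintf("solid %s", name))
    for (i in seq_len(nt)) {
      n <- mesh$normals[i, ]
      v <- mesh$vertices[(3 * i - 2):(3 * i), , drop = FALSE]
      lines <- c(lines,
        sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
        "    endloop", "  endfacet")
    }
    lines <- c(lines, sprintf("endsolid %s", name))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' @param path STL path; the format is auto-detected.
#' @return `Mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary files may also start with "solid"; check the size formula
    sz <- file.size(path)
    con <- file(path, "rb"); on.exit(close(con), add = TRUE)
    seek(con, 80); nt <- readBin(con, "integer", 1, 4, endian = "little")
    close(con); on.exit(NULL)
    sz != 84 + 50 * nt
  }
  if (is_ascii) {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(f) as.numeric(f[2:4]), numeric(3)))
    vertices <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    seek(con, 80)
    nt <- readBin(con, "integer", 1, 4, endian = "little")
    vertices <- matrix(0, 3 * nt, 3)
    for (i in seq_len(nt)) {
      readBin(con, "numeric", 3, size = 4, endian = "little")  # stored normal
      v <- readBin(con, "numeric", 9, size = 4, endian = "little")
      vertices[(3 * i - 2):(3 * i), ] <- matrix(v, 3, 3, byrow = TRUE)
      readBin(con, "integer", 1, size = 2, endian = "little")
    }
  }
  structure(list(vertices = vertices, normals = facet_normals(vertices)),
            class = "Mesh")
}

#' Write a 3D-scene manifest for a set of peptide meshes
#'
#' Records, per peptide, the STL file, display color and triangle count, plus
#' the voxel spacing and downsampling used, as a JSON manifest consumed by
#' external 3D viewers.
#'
#' @param entries data.frame with columns `peptide`, `stl`, `color` (and any
#'   extras).
#' @param path JSON output path.
#' @param spacing,downsample provenance of the volumes.
#' @return `path`, invisibly.
#' @export
write_scene_manifest <- function(entries, path, spacing = c(z = 10, y = 1, x = 1),
                                 downsample = 1L) {
  jsonlite::write_json(list(spacing = as.list(spacing),
                            downsample = downsample,
                            meshes = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
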