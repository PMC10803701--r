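# Isosurface extraction by marching tetrahedra and binary STL export.
#
# Each grid cube is split into 6 tetrahedra sharing the main diagonal; every
# tetrahedron contributes 0, 1 or 2 triangles with vertices linearly
# interpolated onto the zero level set.  The construction is watertight: a
# shared tetrahedron face always receives matching edge intersections, so
# every mesh edge is used by exactly two triangles for a closed surface.

# vertex offsets of a unit cube, index 0..7 (binary x,y,z)
.cube_verts <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                     c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
# 6-tet decomposition along the 0-7 diagonal
.tets <- rbind(c(0,1,3,7), c(0,3,2,7), c(0,2,6,7),
               c(0,6,4,7), c(0,4,5,7), c(0,5,1,7)) + 1L

# Extract triangles of the `field == 0` isosurface.  `field` is a 3D array
# of signed values (positive = inside); xs/ys/zs are voxel-centre coords.
marching_tets <- function(field, xs, ys, zs) {
  eps <- 1e-9 * max(abs(field), 1)
  field[field == 0] <- eps  # avoid iso exactly at a vertex
  n <- dim(field)
  nxc <- n[1] - 1L; nyc <- n[2] - 1L; nzc <- n[3] - 1L
  if (nxc < 1L || nyc < 1L || nzc < 1L) return(matrix(0, 0, 9))
  cube_idx <- as.matrix(expand.grid(ix = seq_len(nxc), iy = seq_len(nyc),
                                    iz = seq_len(nzc)))
  # linear indices of the 8 cube corners for every cube
  lin <- function(ix, iy, iz) ix + n[1] * (iy - 1L) + n[1] * n[2] * (iz - 1L)
  corner_lin <- sapply(1:8, function(v) {
    lin(cube_idx[, 1] + .cube_verts[v, 1],
        cube_idx[, 2] + .cube_verts[v, 2],
        cube_idx[, 3] + .cube_verts[v, 3])
  })
  # skip cubes with uniform sign
  f8 <- matrix(field[corner_lin], ncol = 8)
  active <- rowSums(f8 > 0) %in% 1:7
  if (!any(active)) return(matrix(0, 0, 9))
  corner_lin <- corner_lin[active, , drop = FALSE]
  f8 <- f8[active, , drop = FALSE]
  ci <- cube_idx[active, , drop = FALSE]
  coords <- function(v) {  # ncube x 3 coordinates of cube vertex v
    cbind(xs[ci[, 1] + .cube_verts[v, 1]],
          ys[ci[, 2] + .cube_verts[v, 2]],
          zs[ci[, 3] + .cube_verts[v, 3]])
  }
  vcoord <- lapply(1:8, coords)
  tris <- vector("list", 24)
  tcount <- 0L
  edge_pt <- function(pa, pb, fa, fb) {
    t <- fa / (fa - fb)
    pa + (pb - pa) * t
  }
  for (tt in seq_len(nrow(.tets))) {
    vids <- .tets[tt, ]
    fv <- f8[, vids, drop = FALSE]
    ins <- fv > 0
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      outside <- setdiff(1:4, inside)
      P <- function(k) vcoord[[vids[k]]][sel, , drop = FALSE]
      Fv <- function(k) fv[sel, k]
      if (length(inside) == 1L || length(inside) == 3L) {
        a <- if (length(inside) == 1L) inside else outside
        others <- setdiff(1:4, a)
        e1 <- edge_pt(P(a), P(others[1]), Fv(a), Fv(others[1]))
        e2 <- edge_pt(P(a), P(others[2]), Fv(a), Fv(others[2]))
        e3 <- edge_pt(P(a), P(others[3]), Fv(a), Fv(others[3]))
        tcount <- tcount + 1L; tris[[tcount]] <- cbind(e1, e2, e3)
      } else {  # 2 in / 2 out: quad split into two triangles
        a <- inside[1]; b <- inside[2]; c <- outside[1]; d <- outside[2]
        eac <- edge_pt(P(a), P(c), Fv(a), Fv(c))
        ead <- edge_pt(P(a), P(d), Fv(a), Fv(d))
        ebc <- edge_pt(P(b), P(c), Fv(b), Fv(c))
        ebd <- edge_pt(P(b), P(d), Fv(b), Fv(d))
        tcount <- tcount + 1L; tris[[tcount]] <- cbind(eac, ead, ebd)
        tcount <- tcount + 1L; tris[[tcount]] <- cbind(eac, ebd, ebc)
      }
    }
  }
  do.call(rbind, tris[seq_len(tcount)])
}

#' Export a solid region as a binary STL mesh
#'
#' For a container shape the signed-distance field is sampled at
#' `voxel_size_mm` resolution; for a label volume the solid region (label 2)
#' is meshed at the half-occupancy level.  The mesh is written as binary
#' little-endian STL in mm units.
#'
#' @param x a `container` (with a signed-distance field) or a label
#'   `voxel_volume` from [rasterize_grid()].
#' @param path output `.stl` path.
#' @param voxel_size_mm sampling resolution for container shapes (mm).
#' @return Invisibly, the `n x 9` triangle matrix (three xyz vertices per row).
#' @export
export_stl <- function(x, path, voxel_size_mm = 1) {
  if (inherits(x, "container")) {
    if (is.null(x$sdf_fn))
      stop("container kind '", x$kind, "' has no signed-distance field")
    # offset the lattice by an irrational voxel fraction so the level set
    # almost surely misses lattice vertices (avoids degenerate triangles)
    lo <- x$bbox[1, ] - 2 * voxel_size_mm + (sqrt(2) - 1.4) * voxel_size_mm
    hi <- x$bbox[2, ] + 2 * voxel_size_mm
    nn <- as.integer(ceiling((hi - lo) / voxel_size_mm)) + 1L
    xs <- lo[1] + (seq_len(nn[1]) - 1) * voxel_size_mm
    ys <- lo[2] + (seq_len(nn[2]) - 1) * voxel_size_mm
    zs <- lo[3] + (seq_len(nn[3]) - 1) * voxel_size_mm
    field <- array(x$sdf_fn(xs, ys, zs), dim = nn)
  } else if (inherits(x, "voxel_volume")) {
    solid <- x$values == GRID_LABELS[["solid"]]
    if (!any(solid)) stop("nothing to export: no solid voxels")
    d <- dim(solid) + 2L  # pad so the surface closes at the boundary
    field <- array(-0.5, dim = d)
    field[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
      ifelse(solid, 0.5, -0.5)
    vs <- x$voxel_size_mm
    xs <- x$origin_mm[1] + (seq_len(d[1]) - 2) * vs[1]
    ys <- x$origin_mm[2] + (seq_len(d[2]) - 2) * vs[2]
    zs <- x$origin_mm[3] + (seq_len(d[3]) - 2) * vs[3]
  } else stop("unsupported input for STL export")
  tris <- marching_tets(field, xs, ys, zs)
  if (nrow(tris) == 0) stop("nothing to export: empty isosurface")
  write_stl_binary(tris, path)
  invisible(tris)
}

write_stl_binary <- function(tris, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  v1 <- tris[, 1:3, drop = FALSE]
  v2 <- tris[, 4:6, drop = FALSE]
  v3 <- tris[, 7:9, drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  block <- t(cbind(nrm, v1, v2, v3))  # 12 floats per triangle
  for (i in seq_len(nrow(tris))) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' Surface area of a triangle soup
#' @param tris `n x 9` matrix as returned by [export_stl()].
#' @return Total area (mm^2).
#' @export
mesh_area <- function(tris) {
  e1 <- tris[, 4:6, drop = FALSE] - tris[, 1:3, drop = FALSE]
  e2 <- tris[, 7:9, drop = FALSE] - tris[, 1:3, drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}

#' Check that every mesh edge is shared by exactly two triangles
#' @param tris `n x 9` triangle matrix.
#' @param tol vertex-merge tolerance (mm).
#' @return `TRUE` if the mesh is closed.
#' @export
mesh_is_closed <- function(tris, tol = 1e-6) {
  pts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- apply(round(pts / tol), 1, paste, collapse = ",")
  vid <- match(key, unique(key))
  n <- nrow(tris)
  a <- vid[seq_len(n)]; b <- vid[n + seq_len(n)]; c <- vid[2 * n + seq_len(n)]
  if (any(a == b | b == c | a == c)) return(FALSE)  # degenerate triangle
  edges <- rbind(cbind(pmin(a, b), pmax(a, b)),
                 cbind(pmin(b, c), pmax(b, c)),
                 cbind(pmin(a, c), pmax(a, c)))
  cnt <- table(paste(edges[, 1], edges[, 2]))
  all(cnt == 2L)
}
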