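#' Tetrahedral volume mesh
#'
#' The geometric substrate shared by every component: node coordinates in mm
#' (image frame), 4-node tetrahedral connectivity, and labelled inlet/outlet
#' cap faces on the boundary surface.
#'
#' @param nodes N x 3 numeric matrix of coordinates (mm).
#' @param tets M x 4 integer matrix of 1-based node indices.
#' @param cap_faces named list mapping `inlet`, `outlet_left`, `outlet_right`
#'   to matrices of boundary triangles (1-based node-index triples). May be
#'   empty for meshes without caps (e.g. unit-test fixtures).
#' @param lattice optional lattice metadata attached by the synthetic mesh
#'   builder (used by the analytic flow oracle); carried through untouched.
#' @param validate validate invariants (positive tet volumes, index ranges).
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tets, cap_faces = list(), lattice = NULL,
                        validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (length(tets) == 0L) {
    tets <- matrix(integer(0), 0L, 4L)
  } else {
    tets <- as.matrix(tets)
    storage.mode(tets) <- "integer"
  }
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L)
  m <- structure(
    list(nodes = nodes, tets = tets, cap_faces = cap_faces, lattice = lattice),
    class = "volume_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("<volume_mesh> %d nodes, %d tets, caps: %s\n",
              nrow(x$nodes), nrow(x$tets),
              if (length(x$cap_faces)) paste(names(x$cap_faces), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Validate volume-mesh invariants
#'
#' Checks index ranges, degenerate tets (repeated indices), positive signed
#' volumes, and that cap faces are boundary triangles.
#' @param mesh a `volume_mesh`.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (!all(is.finite(mesh$nodes))) stop("mesh nodes contain non-finite values")
  if (nrow(mesh$tets) > 0L) {
    if (min(mesh$tets) < 1L || max(mesh$tets) > n)
      stop("tet index out of range [1, N]")
    dup <- apply(mesh$tets, 1L, function(r) anyDuplicated(r) > 0L)
    if (any(dup))
      stop(sprintf("degenerate tet with repeated node index (first: tet %d)",
                   which(dup)[1L]))
    v <- tet_volumes(mesh)
    if (any(v <= 0))
      stop(sprintf("non-positive tet volume (first: tet %d, volume %.3g)",
                   which(v <= 0)[1L], min(v)))
  }
  if (length(mesh$cap_faces)) {
    surf <- extract_surface(mesh)
    skey <- apply(surf$triangles, 1L, function(t) paste(sort(t), collapse = "-"))
    for (nm in names(mesh$cap_faces)) {
      f <- mesh$cap_faces[[nm]]
      if (is.null(dim(f)) || nrow(f) < 1L)
        stop(sprintf("cap '%s' has no faces", nm))
      k <- apply(f, 1L, function(t) paste(sort(t), collapse = "-"))
      if (!all(k %in% skey))
        stop(sprintf("cap '%s' contains non-boundary faces", nm))
    }
  }
  invisible(mesh)
}

#' Per-node pressure and velocity fields
#'
#' @param pressure length-N numeric (Pa, gauge).
#' @param velocity N x 3 numeric (m/s).
#' @return An object of class `field_set`.
#' @export
field_set <- function(pressure, velocity) {
  velocity <- as.matrix(velocity)
  stopifnot(length(pressure) == nrow(velocity), ncol(velocity) == 3L)
  if (!all(is.finite(pressure)) || !all(is.finite(velocity)))
    stop("field values must be finite")
  structure(list(pressure = as.numeric(pressure), velocity = velocity),
            class = "field_set")
}

#' Cubic grayscale image volume
#'
#' @param voxels D x D x D numeric array.
#' @param spacing voxel edge length in mm (default 1.0).
#' @param origin mm position of the center of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = 1.0, origin = c(0, 0, 0)) {
  d <- dim(voxels)
  stopifnot(length(d) == 3L, d[1] == d[2], d[2] == d[3], spacing > 0)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Signed tetrahedron volumes
#' @param mesh a `volume_mesh`.
#' @return numeric vector of signed volumes (mm^3), positive when tets are
#'   consistently oriented.
#' @export
tet_volumes <- function(mesh) {
  if (nrow(mesh$tets) == 0L) return(numeric(0))
  p0 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - p0
  b <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - p0
  c3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - p0
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Total mesh volume
#' @param mesh a `volume_mesh`.
#' @return scalar volume (mm^3).
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

#' Unique undirected edges of a tetrahedral mesh
#'
#' Each tet contributes its 6 edges; duplicates are removed and the result is
#' returned with sorted pairs in lexicographic order (deterministic).
#'
#' @param mesh a `volume_mesh`.
#' @return E x 2 integer matrix, `edge[,1] < edge[,2]`.
#' @export
extract_edges <- function(mesh) {
  t <- mesh$tets
  if (nrow(t) == 0L) return(matrix(integer(0), 0L, 2L))
  if (any(apply(t, 1L, anyDuplicated) > 0L))
    stop("degenerate tet with repeated node index")
  pairs <- rbind(t[, c(1, 2)], t[, c(1, 3)], t[, c(1, 4)],
                 t[, c(2, 3)], t[, c(2, 4)], t[, c(3, 4)])
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  key <- (as.numeric(lo) - 1) * nrow(mesh$nodes) + as.numeric(hi)
  keep <- !duplicated(key)
  e <- cbind(lo[keep], hi[keep])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# canonical face key: sorted triple collapsed to a string
.face_key <- function(f) {
  s <- t(apply(f, 1L, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "-")
}

#' Boundary surface of a volume mesh
#'
#' Surface triangles are the tet faces owned by exactly one tet, oriented
#' outward (normal points away from the owning tet's centroid). Faces shared
#' by more than two tets are non-manifold and raise an error.
#'
#' @param mesh a `volume_mesh`.
#' @return An object of class `surface_view` with elements `node_index`
#'   (sorted surface node indices), `triangles` (outward-oriented triples),
#'   and `edges` (unique undirected surface edges, sorted pairs).
#' @export
extract_surface <- function(mesh) {
  t <- mesh$tets
  if (nrow(t) == 0L)
    return(structure(list(node_index = integer(0),
                          triangles = matrix(integer(0), 0, 3),
                          edges = matrix(integer(0), 0, 2)),
                     class = "surface_view"))
  # faces opposite each vertex, oriented so the normal faces outward when the
  # tet is positively oriented
  faces <- rbind(t[, c(2, 4, 3)], t[, c(1, 3, 4)], t[, c(1, 4, 2)], t[, c(1, 2, 3)])
  owner <- rep.int(seq_len(nrow(t)), 4L)
  key <- .face_key(faces)
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1L]
    stop(sprintf("non-manifold face %s shared by %d tets", bad, cnt[[bad]]))
  }
  keep <- key %in% names(cnt)[cnt == 1L]
  tri <- faces[keep, , drop = FALSE]
  own <- owner[keep]
  # enforce outward orientation against the owning tet centroid
  if (nrow(tri) > 0L) {
    for (i in seq_len(nrow(tri))) {
      v <- mesh$nodes[tri[i, ], , drop = FALSE]
      cen <- colMeans(mesh$nodes[t[own[i], ], , drop = FALSE])
      nrm <- .cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
      if (sum(nrm * (colMeans(v) - cen)) < 0) tri[i, ] <- tri[i, c(1, 3, 2)]
    }
  }
  ord <- order(tri[, 1], tri[, 2], tri[, 3])
  tri <- tri[ord, , drop = FALSE]
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  ekey <- paste(lo, hi)
  keepe <- !duplicated(ekey)
  se <- cbind(lo[keepe], hi[keepe])
  se <- se[order(se[, 1], se[, 2]), , drop = FALSE]
  structure(list(node_index = sort(unique(as.vector(tri))),
                 triangles = tri, edges = se),
            class = "surface_view")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Unit normals of triangle faces
#'
#' Normals follow the right-hand rule on the vertex order of each triangle
#' (so triangles from [extract_surface()] yield outward normals).
#'
#' @param mesh a `volume_mesh` supplying coordinates.
#' @param faces K x 3 matrix of node-index triples.
#' @return K x 3 matrix of unit vectors.
#' @export
face_normals <- function(mesh, faces) {
  faces <- matrix(as.integer(faces), ncol = 3L)
  a <- mesh$nodes[faces[, 1], , drop = FALSE]
  b <- mesh$nodes[faces[, 2], , drop = FALSE]
  cc <- mesh$nodes[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len < 1e-12)) stop("zero-area triangle in face list")
  n / len
}

#' Rescaled symmetric-normalized graph Laplacian
#'
#' Builds `L = I - D^(-1/2) A D^(-1/2)` from the mesh edge graph and returns
#' the Chebyshev-rescaled operator `2 L / lambda_max - I` with `lambda_max`
#' fixed at its upper bound 2, i.e. `L - I`, as used by first-order Chebyshev
#' graph convolutions. Isolated nodes get a `-1` diagonal entry (with a
#' warning), keeping the spectrum inside `[-1, 1]`.
#'
#' @param mesh a `volume_mesh` (or a list with `nodes` and `tets`).
#' @param edges optionally, a precomputed E x 2 edge matrix.
#' @return an N x N sparse symmetric `Matrix::dgCMatrix`.
#' @export
scaled_laplacian <- function(mesh, edges = NULL) {
  n <- nrow(mesh$nodes)
  if (is.null(edges)) edges <- extract_edges(mesh)
  if (nrow(edges) == 0L) {
    if (n > 0L) warning("graph has isolated nodes (degree 0)")
    return(Matrix::Diagonal(n, x = rep(-1, n)))
  }
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (any(deg == 0L)) warning("graph has isolated nodes (degree 0)")
  dsq <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  w <- dsq[edges[, 1]] * dsq[edges[, 2]]
  a_norm <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = c(w, w), dims = c(n, n))
  # L = I - Anorm; rescaled: 2L/2 - I = -Anorm ... minus I on diagonal:
  # Ltilde = L - I = -Anorm (for nodes with degree > 0); isolated rows get -1.
  lt <- -a_norm
  Matrix::diag(lt) <- ifelse(deg > 0, 0, -1)
  methods::as(lt, "CsparseMatrix")
}

#' Rasterize a mesh into a binary voxel mask
#'
#' A voxel center is 1 iff it lies inside (or on the boundary of) any
#' tetrahedron, via a barycentric point-in-tet test with tolerance 1e-9.
#'
#' @param mesh a `volume_mesh` (mm coordinates).
#' @param grid an `image_volume` (only dims/spacing/origin are used), or an
#'   integer edge length `D` for a `D^3` unit-spacing grid at origin 0.
#' @return D x D x D integer array of 0/1.
#' @export
voxelize <- function(mesh, grid) {
  if (is.numeric(grid) && length(grid) == 1L)
    grid <- image_volume(array(0, rep(as.integer(grid), 3L)))
  d <- dim(grid$voxels)
  if (nrow(mesh$tets) == 0L || mesh_volume(mesh) <= 0) {
    warning("zero-volume mesh; returning empty mask")
    return(array(0L, d))
  }
  idx <- sweep(mesh$nodes, 2L, grid$origin, "-") / grid$spacing
  lo <- apply(idx, 2L, min); hi <- apply(idx, 2L, max)
  if (any(lo < -0.5) || any(hi > d - 0.5))
    warning("mesh extends beyond grid bounds; mask is clipped")
  .cpp_voxelize_tets(idx, mesh$tets - 1L, as.integer(d), 1e-9)
}

#' Trilinear sampling of feature grids at physical points
#'
#' Maps mm points into grid index space via spacing/origin and interpolates
#' each channel trilinearly. Out-of-bounds points are clamped to the boundary
#' voxel.
#'
#' @param feature_grid D1 x D2 x D3 x C numeric array (a 3D array is treated
#'   as C = 1).
#' @param points K x 3 matrix of mm coordinates.
#' @param spacing mm per voxel of the feature grid.
#' @param origin mm position of the center of voxel (1,1,1).
#' @return K x C matrix of interpolated values.
#' @export
sample_image_features <- function(feature_grid, points, spacing = 1.0,
                                  origin = c(0, 0, 0)) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite point coordinates")
  d <- dim(feature_grid)
  if (length(d) == 3L) { dim(feature_grid) <- c(d, 1L); d <- dim(feature_grid) }
  idx <- sweep(points, 2L, origin, "-") / spacing
  .cpp_trilinear_forward(feature_grid, idx, as.integer(d))
}
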