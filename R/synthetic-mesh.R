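# Parametric Y-shaped vessel anatomies on a fixed lattice. Every case drawn
# from the population shares byte-identical tet connectivity and cap labels
# (point-point correspondence by construction); only node positions move.

#' Anatomy parameters for the synthetic bifurcating vessel
#'
#' Defaults are the population means. `scale = "small"` fits a 32 mm box
#' (CPU-sized tests); `scale = "paper"` fits a 128 mm box at pulmonary-artery
#' dimensions.
#'
#' @param scale `"small"` or `"paper"`.
#' @param trunk_radius,trunk_length mm.
#' @param branch_radius,branch_length length-2, mm.
#' @param half_angle length-2, degrees between trunk axis and each branch.
#' @param curve_amp centerline lateral bow amplitude, mm.
#' @param bump_amp radial bumpiness as a fraction of radius (< 0.5).
#' @return object of class `anatomy_params`.
#' @export
anatomy_params <- function(scale = c("small", "paper"),
                           trunk_radius = NULL, trunk_length = NULL,
                           branch_radius = NULL, branch_length = NULL,
                           half_angle = NULL, curve_amp = NULL,
                           bump_amp = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "small") {
    list(trunk_radius = 4.5, trunk_length = 10,
         branch_radius = c(3.2, 3.0), branch_length = c(9, 9),
         half_angle = c(35, 35), curve_amp = 0.5, bump_amp = 0.04)
  } else {
    list(trunk_radius = 14, trunk_length = 40,
         branch_radius = c(10.5, 10), branch_length = c(36, 36),
         half_angle = c(35, 35), curve_amp = 2, bump_amp = 0.04)
  }
  p <- list(scale = scale,
            trunk_radius = trunk_radius %||% def$trunk_radius,
            trunk_length = trunk_length %||% def$trunk_length,
            branch_radius = branch_radius %||% def$branch_radius,
            branch_length = branch_length %||% def$branch_length,
            half_angle = half_angle %||% def$half_angle,
            curve_amp = curve_amp %||% def$curve_amp,
            bump_amp = bump_amp %||% def$bump_amp)
  stopifnot(p$trunk_radius > 0, p$trunk_length > 0, all(p$branch_radius > 0),
            all(p$branch_length > 0), p$bump_amp < 0.5)
  structure(p, class = "anatomy_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw one anatomy from the synthetic population
#'
#' Radii and lengths vary by +/-15 percent, half-angles by +/-7 degrees,
#' centerline bow uniform in `[0, 2 x default]`, bumpiness in `[0, 0.08]`
#' around the scale defaults: moderate anatomical diversity in the spirit of
#' a mixed congenital-heart-disease population.
#'
#' @param rng an internal `rng_stream`.
#' @param scale `"small"` or `"paper"`.
#' @return an `anatomy_params` draw.
#' @export
sample_anatomy <- function(rng, scale = "small") {
  d <- anatomy_params(scale)
  anatomy_params(
    scale = scale,
    trunk_radius = d$trunk_radius * rng_runif(rng, 1, 0.85, 1.15),
    trunk_length = d$trunk_length * rng_runif(rng, 1, 0.85, 1.15),
    branch_radius = d$branch_radius * rng_runif(rng, 2, 0.85, 1.15),
    branch_length = d$branch_length * rng_runif(rng, 2, 0.85, 1.15),
    half_angle = d$half_angle + rng_runif(rng, 2, -7, 7),
    curve_amp = rng_runif(rng, 1, 0, 2 * d$curve_amp),
    bump_amp = rng_runif(rng, 1, 0, 0.08))
}

#' Lattice resolution of the structured tube mesh
#'
#' @param scale `"small"` (641-node template) or `"paper"` (11,111 nodes,
#'   matching the ~11,000-node working range of pulmonary-artery volume
#'   meshes at this density).
#' @param rings,sectors,trunk_stations,branch_stations override the lattice.
#' @return list with the four counts.
#' @export
mesh_resolution <- function(scale = c("small", "paper"), rings = NULL,
                            sectors = NULL, trunk_stations = NULL,
                            branch_stations = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "small") list(rings = 3L, sectors = 10L,
                                    trunk_stations = 8L, branch_stations = 6L)
         else list(rings = 5L, sectors = 28L,
                   trunk_stations = 26L, branch_stations = 26L)
  r <- list(rings = as.integer(rings %||% def$rings),
            sectors = as.integer(sectors %||% def$sectors),
            trunk_stations = as.integer(trunk_stations %||% def$trunk_stations),
            branch_stations = as.integer(branch_stations %||% def$branch_stations))
  stopifnot(r$rings >= 2L, r$sectors >= 8L, r$trunk_stations >= 5L,
            r$branch_stations >= 3L)
  r
}

#' Node/cell counts implied by a lattice resolution
#' @param res a [mesh_resolution()].
#' @return list with `nodes_per_station`, `n_nodes`, `n_tets`.
#' @export
lattice_counts <- function(res) {
  p <- 1L + res$rings * res$sectors
  nst <- res$trunk_stations + 2L * res$branch_stations
  gaps <- (res$trunk_stations - 1L) + 2L * res$branch_stations
  list(nodes_per_station = p,
       n_nodes = p * (nst + 1L) - res$sectors,
       n_tets = 3L * res$sectors * (2L * res$rings - 1L) * gaps)
}

# triangulate the lattice disk (local 0-based indices; 0 = center,
# ring i sector j -> 1 + (i-1)*S + j). Quad diagonals follow the
# min-local-index corner, matching the global min-vertex prism rule.
.disk_triangles <- function(rings, sectors) {
  tri <- list()
  for (j in 0:(sectors - 1L)) {
    jn <- (j + 1L) %% sectors
    tri[[length(tri) + 1L]] <- c(0L, 1L + j, 1L + jn)
  }
  ring_id <- function(i, j) 1L + (i - 1L) * sectors + (j %% sectors)
  for (i in 1:(rings - 1L)) {
    for (j in 0:(sectors - 1L)) {
      a <- ring_id(i, j); b <- ring_id(i, j + 1L)
      cc <- ring_id(i + 1L, j + 1L); d <- ring_id(i + 1L, j)
      if (min(a, cc) < min(b, d)) {
        tri[[length(tri) + 1L]] <- c(a, cc, b)
        tri[[length(tri) + 1L]] <- c(a, d, cc)
      } else {
        tri[[length(tri) + 1L]] <- c(a, d, b)
        tri[[length(tri) + 1L]] <- c(b, d, cc)
      }
    }
  }
  do.call(rbind, tri)
}

# Dompierre et al. prism-to-3-tets split keyed on global vertex indices;
# guarantees matching diagonals on quad faces shared between prisms.
.prism_rotations <- matrix(c(
  0, 1, 2, 3, 4, 5,
  1, 2, 0, 4, 5, 3,
  2, 0, 1, 5, 3, 4,
  3, 5, 4, 0, 2, 1,
  4, 3, 5, 1, 0, 2,
  5, 4, 3, 2, 1, 0) + 1L, ncol = 6L, byrow = TRUE)

.split_prism <- function(v) {
  rot <- .prism_rotations[which.min(v), ]
  w <- v[rot]
  if (min(w[2], w[6]) < min(w[3], w[5])) {
    rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
  } else {
    rbind(w[c(1, 2, 3, 5)], w[c(1, 5, 3, 6)], w[c(1, 5, 6, 4)])
  }
}

.smoothstep <- function(x) { x <- pmin(1, pmax(0, x)); x * x * (3 - 2 * x) }

# disk frame perpendicular to tangent tv (tangents stay well away from +y)
.disk_frame <- function(tv) {
  e1 <- .cross3(c(0, 1, 0), tv)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(tv, e1)
  list(e1 = e1, e2 = e2 / sqrt(sum(e2^2)))
}

#' Build a point-correspondent Y-vessel tetrahedral mesh
#'
#' Nodes sit on a fixed (segment, station, ring, sector) lattice deformed by
#' the anatomy parameters, so any two parameter draws at the same resolution
#' produce identical connectivity. The first branch continues conformally off
#' the trunk-end (junction) disk; the second branch is welded to the junction
#' wall ring but carries its own copy of the disk interior (a thin internal
#' septum), which keeps every tet face shared by at most two tets -- an
#' interior cross-section disk can only bound two cell layers, so a full
#' three-way disk weld would be non-manifold. Caps are the inlet disk (trunk
#' start) and the two branch-end disks.
#'
#' With `rings` R, `sectors` S, `trunk_stations` T and `branch_stations` B,
#' the mesh has `(T + 2B + 1)(1 + RS) - S` nodes.
#'
#' @param params an [anatomy_params()].
#' @param res a [mesh_resolution()]; defaults to the params' scale.
#' @param center mm point at which to center the mesh bounding box.
#' @return a `volume_mesh` with `lattice` metadata used by [analytic_flow()].
#' @export
build_structured_tube_mesh <- function(params, res = NULL, center = c(0, 0, 0)) {
  res <- res %||% mesh_resolution(params$scale)
  R <- res$rings; S <- res$sectors
  TT <- res$trunk_stations; B <- res$branch_stations
  P <- 1L + R * S
  Pint <- P - S                        # disk interior (center + rings < R)
  phi <- params$half_angle * pi / 180
  dirs <- list(c(sin(phi[1]), 0, cos(phi[1])), c(-sin(phi[2]), 0, cos(phi[2])))
  end1 <- params$branch_length[1] * dirs[[1]]
  end2 <- params$branch_length[2] * dirs[[2]]
  if (sqrt(sum((end1 - end2)^2)) < 0.8 * sum(params$branch_radius))
    stop(sprintf(paste0("branch half-angles (%.1f, %.1f deg) too small for radii ",
                        "(%.2f, %.2f mm): branches self-intersect"),
                 params$half_angle[1], params$half_angle[2],
                 params$branch_radius[1], params$branch_radius[2]))

  # logical station rows: trunk 1..TT, branch1 1..B, septum copy of the
  # junction disk (branch2 station 0), branch2 1..B
  n_rows <- TT + 2L * B + 1L
  j2_row <- TT + B + 1L
  row_np <- rep(P, n_rows); row_np[j2_row] <- Pint
  row_base <- cumsum(c(0L, row_np))[seq_len(n_rows)]
  n_nodes <- sum(row_np)

  nodes <- matrix(0, n_nodes, 3L)
  seg_of <- integer(n_rows); st_of <- integer(n_rows)
  centers <- matrix(0, n_rows, 3L); tangents <- matrix(0, n_rows, 3L)
  fracs <- numeric(n_rows); radii <- numeric(n_rows)

  disk_points <- function(cen, tv, r_nom, tfrac) {
    fr <- .disk_frame(tv)
    pts <- matrix(0, P, 3L)
    pts[1L, ] <- cen
    k <- 2L
    for (i in 1:R) {
      for (j in 0:(S - 1L)) {
        th <- 2 * pi * j / S
        rb <- r_nom * (1 + params$bump_amp * sin(3 * th + 2 * pi * tfrac))
        pts[k, ] <- cen + (i / R) * rb * (cos(th) * fr$e1 + sin(th) * fr$e2)
        k <- k + 1L
      }
    }
    pts
  }
  fill_row <- function(row, cen, tv, r_nom, tfrac, seg, st, n_keep = P) {
    pts <- disk_points(cen, tv, r_nom, tfrac)
    nodes[row_base[row] + seq_len(n_keep), ] <<- pts[seq_len(n_keep), , drop = FALSE]
    centers[row, ] <<- cen; tangents[row, ] <<- tv
    fracs[row] <<- tfrac; radii[row] <<- r_nom
    seg_of[row] <<- seg; st_of[row] <<- st
  }

  # trunk: inlet at row 1, junction disk at row TT; axis +z with a sinusoidal
  # x-bow vanishing at both ends
  junction <- c(0, 0, 0)
  for (s in 0:(TT - 1L)) {
    t <- s / (TT - 1L)
    cen <- junction + c(params$curve_amp * sin(pi * t), 0,
                        -params$trunk_length * (1 - t))
    tv <- c(params$curve_amp * pi * cos(pi * t) / params$trunk_length, 0, 1)
    fill_row(s + 1L, cen, tv / sqrt(sum(tv^2)), params$trunk_radius, t, 0L, s)
  }
  t_end <- tangents[TT, ]

  # branches: disk orientations rotate gradually (linear blend over the first
  # half of the branch) from the trunk-end tangent to the branch direction,
  # keeping the per-gap rotation small so no prism inverts at the weld
  branch_row <- function(b, s) if (b == 1L) TT + s else j2_row + s
  for (b in 1:2) {
    dvec <- dirs[[b]]
    perp <- .disk_frame(dvec)$e2
    for (s in 1:B) {
      u <- s / B
      cen <- junction + u * params$branch_length[b] * dvec +
        params$curve_amp * 0.5 * sin(pi * u) * perp
      tvb <- params$branch_length[b] * dvec +
        params$curve_amp * 0.5 * pi * cos(pi * u) * perp
      tvb <- tvb / sqrt(sum(tvb^2))
      w <- u  # full-branch linear blend: ~6 deg of disk rotation per gap
      tv <- (1 - w) * t_end + w * tvb
      tv <- tv / sqrt(sum(tv^2))
      r_nom <- params$trunk_radius +
        (params$branch_radius[b] - params$trunk_radius) * .smoothstep(u / 0.5)
      fill_row(branch_row(b, s), cen, tv, r_nom, u, b, s)
    }
  }
  # septum: interior copy of the junction disk (branch2 station 0)
  fill_row(j2_row, centers[TT, ], tangents[TT, ], radii[TT], 0, 2L, 0L,
           n_keep = Pint)

  # prism gaps; each side of a gap maps local disk index (0-based) -> global
  plain_map <- function(row) function(k) row_base[row] + k + 1L
  septum_map <- function(k) ifelse(k < Pint, row_base[j2_row] + k + 1L,
                                   row_base[TT] + k + 1L)
  gaps <- c(
    lapply(seq_len(TT - 1L), function(s) list(plain_map(s), plain_map(s + 1L))),
    lapply(seq_len(B), function(s) list(
      if (s == 1L) plain_map(TT) else plain_map(branch_row(1L, s - 1L)),
      plain_map(branch_row(1L, s)))),
    lapply(seq_len(B), function(s) list(
      if (s == 1L) septum_map else plain_map(branch_row(2L, s - 1L)),
      plain_map(branch_row(2L, s)))))

  disk <- .disk_triangles(R, S)
  tets <- matrix(0L, 3L * nrow(disk) * length(gaps), 4L)
  ti <- 1L
  for (g in gaps) {
    for (d in seq_len(nrow(disk))) {
      tr <- disk[d, ]
      split <- .split_prism(c(g[[1]](tr), g[[2]](tr)))
      tets[ti:(ti + 2L), ] <- split
      ti <- ti + 3L
    }
  }
  # orientation is topological: disk triangles are CCW in the (e1, e2) frame
  # and prisms extrude along +tangent, so every tet is positively oriented
  # for any non-folding parameter draw (validate_mesh() errors otherwise);
  # the connectivity therefore never depends on the draw.

  # cap faces wound topologically: CCW disk normals point along +tangent,
  # which is outward at the outlets and inward at the inlet (reverse there)
  cap_at <- function(row, reverse = FALSE) {
    f <- matrix(row_base[row] + as.integer(disk) + 1L, ncol = 3L)
    if (reverse) f <- f[, c(1, 3, 2), drop = FALSE]
    f
  }
  cap_faces <- list(
    inlet = cap_at(1L, reverse = TRUE),
    outlet_left = cap_at(branch_row(1L, B)),
    outlet_right = cap_at(branch_row(2L, B)))

  bb_mid <- (apply(nodes, 2L, max) + apply(nodes, 2L, min)) / 2
  shift <- center - bb_mid
  nodes <- sweep(nodes, 2L, shift, "+")
  centers <- sweep(centers, 2L, shift, "+")

  # flow directions use the same centered-difference tangent rule as
  # attach_lattice(), so re-fit lattices reproduce the flow oracle exactly
  flow_tangents <- .lattice_tangents(centers, seg_of, st_of, TT, B, branch_row)
  ring_full <- c(0L, rep(1:R, each = S))
  sector_full <- c(0L, rep(0:(S - 1L), R))
  per_row <- function(x) unlist(lapply(seq_len(n_rows), function(r)
    rep(x[r], row_np[r])))
  lattice <- list(res = res, params = params,
                  node_seg = per_row(seg_of),
                  node_station = per_row(st_of),
                  node_ring = unlist(lapply(row_np, function(np) ring_full[seq_len(np)])),
                  node_sector = unlist(lapply(row_np, function(np) sector_full[seq_len(np)])),
                  station_row = per_row(seq_len(n_rows)),
                  row_base = row_base, row_np = row_np, j2_row = j2_row,
                  centers = centers, tangents = flow_tangents,
                  fracs = fracs, radii = radii,
                  seg_of_row = seg_of, st_of_row = st_of)
  volume_mesh(nodes, tets, cap_faces, lattice = lattice)
}
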