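# Analytic steady laminar flow on the lattice mesh: Hagen-Poiseuille per
# segment, parallel-resistance flow split at the bifurcation, 0 Pa gauge
# outlets, parabolic no-slip velocity profiles. The fields are exactly linear
# in the inlet velocity, which is the structure the network must learn.

#' Closed-form Poiseuille pressure drop
#'
#' `dp = 8 mu L Q / (pi r^4)` in SI units.
#'
#' @param radius_mm,length_mm segment geometry in mm.
#' @param flow_m3s volumetric flow in m^3/s.
#' @param viscosity Pa s.
#' @return pressure drop in Pa.
#' @export
poiseuille_dp <- function(radius_mm, length_mm, flow_m3s, viscosity = 0.04) {
  r <- radius_mm * 1e-3; l <- length_mm * 1e-3
  8 * viscosity * l * flow_m3s / (pi * r^4)
}

#' Analytic flow field on a lattice vessel mesh
#'
#' Inlet flow `Q = v_in pi r_trunk^2` splits between the branches in
#' proportion to the inverse Poiseuille resistances `8 mu L / (pi r^4)`;
#' pressure drops linearly along each segment's stations from the inlet value
#' to exactly 0 Pa gauge at the outlets; nodal velocity points along the local
#' centerline tangent with the parabolic profile `2 v_mean (1 - (rho/r)^2)`.
#' Velocity direction and mean blend smoothly across the junction region
#' (first quarter of each branch). Everything scales exactly linearly with
#' the inlet velocity.
#'
#' @param mesh a `volume_mesh` from [build_structured_tube_mesh()] (needs the
#'   lattice metadata).
#' @param inlet_velocity mean inlet velocity, m/s (> 0).
#' @param viscosity dynamic viscosity, Pa s (blood default 0.04).
#' @param density kg/m^3 (blood default 1060; carried for interface
#'   completeness -- steady Poiseuille pressure depends only on viscosity).
#' @return a `field_set`; attribute `flow` holds the segment summary
#'   (`Q_in`, `Q_branch`, `p_inlet`, `p_junction`).
#' @export
analytic_flow <- function(mesh, inlet_velocity, viscosity = 0.04,
                          density = 1060) {
  if (inlet_velocity <= 0) stop("inlet velocity must be positive")
  lat <- mesh$lattice
  if (is.null(lat)) stop("mesh has no lattice metadata (not a synthetic lattice mesh)")
  params <- lat$params
  r_t <- params$trunk_radius * 1e-3
  q_in <- inlet_velocity * pi * r_t^2
  r_b <- params$branch_radius * 1e-3
  l_b <- params$branch_length * 1e-3
  res_b <- 8 * viscosity * l_b / (pi * r_b^4)
  g <- 1 / res_b
  q_b <- q_in * g / sum(g)                     # exact conservation
  p_junction <- q_b[1] * res_b[1]              # equal for both branches
  p_inlet <- p_junction + poiseuille_dp(params$trunk_radius,
                                        params$trunk_length, q_in, viscosity)
  v_mean <- c(inlet_velocity, q_b / (pi * r_b^2))  # per segment (trunk, b1, b2)

  n <- nrow(mesh$nodes)
  seg <- lat$node_seg
  row <- lat$station_row
  frac <- lat$fracs[row]
  ring <- lat$node_ring
  rr <- lat$res$rings
  tang <- lat$tangents[row, , drop = FALSE]

  pressure <- numeric(n)
  tr <- seg == 0L
  pressure[tr] <- p_inlet - (p_inlet - p_junction) * frac[tr]
  pressure[!tr] <- p_junction * (1 - frac[!tr])

  # junction blending of mean velocity and direction over the first quarter
  # of each branch (trunk-end tangent/mean -> branch tangent/mean)
  vmag_mean <- v_mean[seg + 1L]
  dirs <- tang
  t_end <- lat$tangents[lat$res$trunk_stations, ]
  bl <- !tr & frac <= 0.25
  if (any(bl)) {
    w <- frac[bl] / 0.25
    vmag_mean[bl] <- (1 - w) * v_mean[1] + w * v_mean[seg[bl] + 1L]
    dirs[bl, ] <- (1 - w) * matrix(t_end, sum(bl), 3, byrow = TRUE) +
      w * dirs[bl, , drop = FALSE]
    dirs[bl, ] <- dirs[bl, , drop = FALSE] /
      sqrt(rowSums(dirs[bl, , drop = FALSE]^2))
  }
  vmag <- 2 * vmag_mean * (1 - (ring / rr)^2)
  velocity <- dirs * vmag
  f <- field_set(pressure, velocity)
  attr(f, "flow") <- list(Q_in = q_in, Q_branch = q_b,
                          p_inlet = p_inlet, p_junction = p_junction,
                          viscosity = viscosity, density = density)
  f
}
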