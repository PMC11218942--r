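# Template construction by node-averaging, direct deformation-fitting of the
# template to a non-correspondent target point set, and barycentric field
# interpolation between meshes.

#' Average a set of point-correspondent meshes into a template
#'
#' Node-wise arithmetic mean of coordinates; tets and cap labels are copied
#' from the first mesh. Errors if any mesh disagrees in topology or if
#' averaging inverts cells.
#'
#' @param meshes list of `volume_mesh` sharing topology.
#' @return a `volume_mesh`; lattice metadata is re-fit when the inputs carry it.
#' @export
average_template <- function(meshes) {
  if (!length(meshes)) stop("no meshes supplied")
  ref <- meshes[[1]]
  for (i in seq_along(meshes)) {
    if (!identical(meshes[[i]]$tets, ref$tets) ||
        nrow(meshes[[i]]$nodes) != nrow(ref$nodes))
      stop(sprintf("mesh %d does not share the template topology", i))
  }
  nodes <- Reduce(`+`, lapply(meshes, `[[`, "nodes")) / length(meshes)
  out <- volume_mesh(nodes, ref$tets, ref$cap_faces)
  if (!is.null(ref$lattice)) out <- attach_lattice(out, ref$lattice$res)
  out
}

#' Fit a template mesh to a target surface point cloud
#'
#' Direct gradient-based deformation (no network): minimizes the surface
#' Chamfer term plus the mesh-quality regularizers
#' `lambda1 (L_point + L_point,S) + lambda2 (L_edge + L_edge,S) +
#'  lambda3 L_aspect + lambda4 L_cap`
#' over the node positions with Adam. `L_point` compares all nodes against
#' `target_volume_points` when given, otherwise it is dropped (surface-only
#' targets).
#'
#' @param template a `volume_mesh`.
#' @param target_points K x 3 matrix of target surface points (mm).
#' @param weights a [loss_weights()] (lambda5 is ignored).
#' @param target_volume_points optional L x 3 interior+surface point set.
#' @param max_iter,tol convergence: stop when the relative loss change over a
#'   20-iteration window drops below `tol`.
#' @param lr Adam step size (mm-scale coordinates).
#' @param align translate the template onto the target centroid before the
#'   free-node optimization (removes rigid offsets that would otherwise trap
#'   the nearest-neighbour assignment).
#' @return a `deformation_fit`: `nodes`, `mesh`, `residual` (final surface
#'   Chamfer), `iterations`, `converged`, `loss_trace`.
#' @export
fit_correspondence <- function(template, target_points,
                               weights = loss_weights(),
                               target_volume_points = NULL,
                               max_iter = 2000L, tol = 1e-6, lr = 0.05,
                               align = TRUE) {
  target_points <- as.matrix(target_points)
  if (nrow(target_points) == 0L) stop("empty target point set")
  topo <- loss_topology(template)
  x <- template$nodes
  if (align) {
    surf0 <- x[topo$surf_nodes, , drop = FALSE]
    x <- sweep(x, 2L, colMeans(target_points) - colMeans(surf0), "+")
  }
  adam <- .adam_new(list(x = x), lr = lr)
  trace <- numeric(0)
  init_loss <- NA_real_
  converged <- FALSE
  chamfer_val <- NA_real_
  for (it in seq_len(max_iter)) {
    tape <- ad_tape()
    coords <- ad_input(tape, x)
    sidx <- topo$surf_nodes
    surf_nodes <- ad_index_rows(tape, coords, sidx)
    point_s <- tape_chamfer(tape, surf_nodes, target_points)
    loss <- ad_mul(tape, point_s, weights$lambda1)
    if (!is.null(target_volume_points)) {
      pt <- tape_chamfer(tape, coords, as.matrix(target_volume_points))
      loss <- ad_add(tape, loss, ad_mul(tape, pt, weights$lambda1))
    }
    if (weights$lambda2 > 0) {
      ed <- ad_add(tape, tape_edge_deviation(tape, coords, topo$edges),
                   tape_edge_deviation(tape, coords, topo$surf_edges))
      loss <- ad_add(tape, loss, ad_mul(tape, ed, weights$lambda2))
    }
    if (weights$lambda3 > 0)
      loss <- ad_add(tape, loss,
                     ad_mul(tape, tape_aspect(tape, coords, topo$tets),
                            weights$lambda3))
    if (weights$lambda4 > 0 && length(topo$cap_faces) == 3L)
      loss <- ad_add(tape, loss,
                     ad_mul(tape, tape_cap(tape, coords, topo$cap_faces),
                            weights$lambda4))
    ad_backward(tape, loss)
    trace[it] <- loss$value
    chamfer_val <- point_s$value
    if (it == 1L) init_loss <- loss$value
    if (loss$value > 10 * init_loss + 1e-12)
      stop("deformation fit diverged (loss grew 10x): reduce the step size")
    upd <- .adam_step(adam, list(x = coords$grad))
    x <- upd$x
    if (it > 20L) {
      w0 <- trace[it - 20L]
      if (abs(w0 - trace[it]) <= tol * max(abs(w0), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  mesh <- volume_mesh(x, template$tets, template$cap_faces, validate = FALSE)
  structure(list(nodes = x, mesh = mesh, residual = chamfer_val,
                 iterations = length(trace), converged = converged,
                 loss_trace = trace),
            class = "deformation_fit")
}

#' Interpolate nodal fields from a source mesh onto query points
#'
#' Each query is located in a containing tetrahedron (lowest tet index on
#' ties) and interpolated barycentrically -- exact for affine fields.
#' Queries outside the source mesh fall back to the nearest source node;
#' their count is reported in the `outside` attribute.
#'
#' @param source_mesh a `volume_mesh`.
#' @param source_fields a `field_set` on the source mesh.
#' @param query_points K x 3 matrix (mm).
#' @return a `field_set` at the queries, with attribute `outside`.
#' @export
interpolate_fields <- function(source_mesh, source_fields, query_points) {
  if (nrow(source_mesh$nodes) == 0L) stop("empty source mesh")
  q <- as.matrix(query_points)
  loc <- .cpp_find_tet(source_mesh$nodes, source_mesh$tets - 1L, q, 1e-9)
  vals <- cbind(source_fields$pressure, source_fields$velocity)
  out <- matrix(0, nrow(q), 4L)
  inside <- !is.na(loc$tet)
  if (any(inside)) {
    ti <- loc$tet[inside]
    b <- loc$bary[inside, , drop = FALSE]
    for (k in 1:4) {
      idx <- source_mesh$tets[ti, k]
      out[inside, ] <- out[inside, ] + b[, k] * vals[idx, , drop = FALSE]
    }
  }
  if (any(!inside)) {
    nn <- .cpp_nn_index(q[!inside, , drop = FALSE], source_mesh$nodes)
    out[!inside, ] <- vals[nn, , drop = FALSE]
  }
  f <- field_set(out[, 1], out[, 2:4, drop = FALSE])
  attr(f, "outside") <- sum(!inside)
  f
}
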