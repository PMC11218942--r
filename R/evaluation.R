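# Segmentation metrics (Dice / ASSD / Hausdorff), node-wise flow error
# metrics (NAE, MNAE_s, MNAE_n), Bland-Altman agreement, and the
# error-decomposition report separating geometry error from flow-prediction
# error.

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined as identical
#' (Dice 1, with a warning).
#' @param a,b binary arrays on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

.surface_tri_matrix <- function(mesh, surf = NULL) {
  if (is.null(surf)) surf <- extract_surface(mesh)
  tri <- surf$triangles
  cbind(mesh$nodes[tri[, 1], , drop = FALSE],
        mesh$nodes[tri[, 2], , drop = FALSE],
        mesh$nodes[tri[, 3], , drop = FALSE])
}

.directed_surf_dists <- function(mesh_a, mesh_b, surf_a = NULL, surf_b = NULL) {
  if (is.null(surf_a)) surf_a <- extract_surface(mesh_a)
  if (nrow(surf_a$triangles) == 0L) stop("empty surface")
  pts <- mesh_a$nodes[surf_a$node_index, , drop = FALSE]
  .cpp_point_tri_dist(pts, .surface_tri_matrix(mesh_b, surf_b))
}

#' Average symmetric surface distance (mm)
#'
#' Mean over all surface vertices of both meshes of the distance to the other
#' mesh's surface triangles.
#' @param mesh_a,mesh_b `volume_mesh`es.
#' @param surf_a,surf_b optional precomputed [extract_surface()] views.
#' @return scalar mm.
#' @export
assd <- function(mesh_a, mesh_b, surf_a = NULL, surf_b = NULL) {
  da <- .directed_surf_dists(mesh_a, mesh_b, surf_a, surf_b)
  db <- .directed_surf_dists(mesh_b, mesh_a, surf_b, surf_a)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' Hausdorff surface distance (mm)
#'
#' Maximum over both directions of the point-to-surface distance; with
#' `percentile = 95` the robust 95th-percentile variant.
#' @inheritParams assd
#' @param percentile 100 (true maximum, default) or another percentile.
#' @return scalar mm.
#' @export
hausdorff <- function(mesh_a, mesh_b, surf_a = NULL, surf_b = NULL,
                      percentile = 100) {
  da <- .directed_surf_dists(mesh_a, mesh_b, surf_a, surf_b)
  db <- .directed_surf_dists(mesh_b, mesh_a, surf_b, surf_a)
  if (percentile >= 100) max(da, db)
  else max(stats::quantile(da, percentile / 100),
           stats::quantile(db, percentile / 100))
}

.nae_channels <- function(f) {
  m <- cbind(f$pressure, sqrt(rowSums(f$velocity^2)), f$velocity)
  colnames(m) <- c("pressure", "vmag", "vx", "vy", "vz")
  m
}

#' Node-wise normalized absolute error (percent)
#'
#' `NAE_j = 100 |pred_j - truth_j| / (max(truth) - min(truth))` per channel
#' (pressure, velocity magnitude, vx, vy, vz), with the denominator taken per
#' subject and per channel. This range normalization amplifies percentage
#' errors when the subject's fields are small (e.g. low inlet velocities).
#'
#' @param pred,truth `field_set`s in point correspondence.
#' @return N x 5 matrix of percentages.
#' @export
nae <- function(pred, truth) {
  pm <- .nae_channels(pred); tm <- .nae_channels(truth)
  if (nrow(pm) != nrow(tm)) stop("field length mismatch")
  rng <- apply(tm, 2L, function(x) max(x) - min(x))
  if (any(rng <= 0))
    stop("constant truth channel (zero range): ",
         paste(colnames(tm)[rng <= 0], collapse = ", "))
  sweep(abs(pm - tm), 2L, rng, "/") * 100
}

#' Subject-level mean NAE
#' @param nae_mat an [nae()] matrix.
#' @return named vector: mean over nodes per channel (percent).
#' @export
mnae_subject <- function(nae_mat) {
  if (!nrow(nae_mat)) stop("empty NAE matrix")
  colMeans(nae_mat)
}

#' Node-level mean NAE across subjects
#' @param nae_list list of [nae()] matrices on the shared template topology.
#' @return N x 5 matrix: mean over subjects per node (percent).
#' @export
mnae_node <- function(nae_list) {
  if (!length(nae_list)) stop("no cases supplied")
  n <- nrow(nae_list[[1]])
  for (m in nae_list) if (nrow(m) != n) stop("non-correspondent NAE matrices")
  Reduce(`+`, nae_list) / length(nae_list)
}

#' Bland-Altman bias and limits of agreement
#' @param pred,truth paired numeric vectors (>= 3 points).
#' @return list with `bias`, `loa` (lower, upper at 1.96 population sd).
#' @export
bland_altman <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 paired values")
  d <- pred - truth
  bias <- mean(d)
  s <- sqrt(mean((d - bias)^2))
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s))
}

#' Decompose prediction error into geometry and flow components
#'
#' Compares the model's direct flow prediction against the flow oracle run on
#' the model's own predicted geometry (the desk-scale analogue of running
#' conventional CFD on a deep-learning segmentation): anatomy parameters are
#' re-fit to the predicted mesh through its lattice landmarks and the
#' analytic Poiseuille solution is evaluated on it. Negative differences mean
#' the direct prediction outperforms oracle-on-predicted-geometry.
#'
#' @param pred_mesh predicted `volume_mesh` (template lattice topology).
#' @param pred_fields predicted `field_set` (physical units).
#' @param truth_fields ground-truth `field_set` on the correspondent mesh.
#' @param inlet_velocity the inlet velocity the prediction was run at (m/s).
#' @param res the [mesh_resolution()] of the lattice.
#' @return list with `delta` (MNAE_s difference per channel, percent),
#'   `mnae_direct`, `mnae_oracle`.
#' @export
error_decomposition <- function(pred_mesh, pred_fields, truth_fields,
                                inlet_velocity, res) {
  oracle_mesh <- attach_lattice(
    volume_mesh(pred_mesh$nodes, pred_mesh$tets, pred_mesh$cap_faces,
                validate = FALSE), res)
  oracle_fields <- analytic_flow(oracle_mesh, inlet_velocity)
  m_direct <- mnae_subject(nae(pred_fields, truth_fields))
  m_oracle <- mnae_subject(nae(oracle_fields, truth_fields))
  list(delta = m_direct - m_oracle, mnae_direct = m_direct,
       mnae_oracle = m_oracle)
}

#' Evaluate predictions against ground truth for a set of cases
#'
#' @param preds list per case: `mesh` (`volume_mesh`), `fields` (`field_set`).
#' @param truths list per case: `mesh`, `fields`, `mask` (binary array).
#' @param grid an `image_volume` spec (or edge length) for voxelization.
#' @return list with per-case data.frame `cases` (dice, assd, hd, MNAE_s per
#'   channel), `mnae_node` matrix, and `bland_altman` per channel.
#' @export
evaluate_cases <- function(preds, truths, grid) {
  stopifnot(length(preds) == length(truths))
  rows <- NULL
  nae_list <- list()
  ba_pred <- NULL; ba_truth <- NULL
  for (i in seq_along(preds)) {
    pr <- preds[[i]]; tr <- truths[[i]]
    pmask <- suppressWarnings(voxelize(pr$mesh, grid))
    nm <- nae(pr$fields, tr$fields)
    nae_list[[i]] <- nm
    ms <- mnae_subject(nm)
    rows <- rbind(rows, data.frame(
      case = i,
      dice = dice(pmask, tr$mask),
      assd = assd(pr$mesh, tr$mesh),
      hd = hausdorff(pr$mesh, tr$mesh),
      mnae_pressure = ms[["pressure"]], mnae_vmag = ms[["vmag"]],
      mnae_vx = ms[["vx"]], mnae_vy = ms[["vy"]], mnae_vz = ms[["vz"]]))
    ba_pred <- rbind(ba_pred, .nae_channels(pr$fields))
    ba_truth <- rbind(ba_truth, .nae_channels(tr$fields))
  }
  ba <- lapply(colnames(ba_pred), function(ch)
    bland_altman(ba_pred[, ch], ba_truth[, ch]))
  names(ba) <- colnames(ba_pred)
  list(cases = rows, mnae_node = mnae_node(nae_list), bland_altman = ba)
}
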