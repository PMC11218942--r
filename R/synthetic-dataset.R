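# Seeded dataset generation and loading. Every case shares one lattice
# resolution (hence identical tets and cap labels); randomness flows from a
# master seed through per-case derived seeds so partial regeneration is
# stable; a manifest records every file with its md5 hash.

.grid_size_for <- function(scale) if (scale == "small") 32L else 128L

#' Generate a synthetic training dataset on disk
#'
#' Per case: an anatomy draw, its lattice mesh, pseudo-MRI image + mask, and
#' one analytic flow field per drawn inlet velocity (normal with the given
#' mean/sd, truncated at 0.02 m/s). Test-split cases additionally get a
#' fixed-velocity sweep (default 0.1/0.2/0.3 m/s) for the inlet-response
#' experiment.
#'
#' @param dir output directory (created).
#' @param n_cases total cases; must cover `sum(split)`.
#' @param split integer (train, val, test) sizes.
#' @param master_seed integer seed controlling everything.
#' @param scale `"small"` (32^3 grid, ~620-node meshes) or `"paper"` (128^3,
#'   10,998-node meshes).
#' @param inlet_mean,inlet_sd inlet-velocity distribution (m/s).
#' @param n_velocities flow fields per training case.
#' @param sweep fixed test-case sweep velocities (m/s).
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
generate_dataset <- function(dir, n_cases, split = NULL, master_seed = 1L,
                             scale = c("small", "paper"),
                             inlet_mean = 0.2, inlet_sd = 0.05,
                             n_velocities = 4L, sweep = c(0.1, 0.2, 0.3)) {
  scale <- match.arg(scale)
  if (is.null(split)) {
    split <- if (scale == "small") c(40L, 8L, 8L) else c(110L, 10L, 15L)
    if (n_cases < sum(split)) {
      # proportional fallback for small exploratory datasets
      te <- max(1L, round(0.15 * n_cases))
      va <- max(1L, round(0.15 * n_cases))
      split <- c(n_cases - va - te, va, te)
      if (split[1] < 1L) stop("need at least 3 cases")
    }
  }
  if (n_cases < sum(split)) stop("n_cases smaller than the split sum")
  d <- .grid_size_for(scale)
  res <- mesh_resolution(scale)
  ids <- sprintf("case_%03d", seq_len(n_cases))
  if (anyDuplicated(ids)) stop("case id collision")
  split_ids <- list(train = ids[seq_len(split[1])],
                    val = ids[split[1] + seq_len(split[2])],
                    test = ids[split[1] + split[2] + seq_len(split[3])])
  dir.create(file.path(dir, "cases"), recursive = TRUE, showWarnings = FALSE)
  center <- rep((d - 1) / 2, 3L)
  cases <- list()
  for (i in seq_len(n_cases)) {
    id <- ids[i]
    case_seed <- derive_seed(master_seed, "case", id)
    rng <- rng_stream(case_seed)
    params <- sample_anatomy(rng, scale)
    mesh <- build_structured_tube_mesh(params, res, center = center)
    pm <- rasterize_pseudo_mri(mesh, d, seed = derive_seed(case_seed, "image"))
    vels <- pmax(0.02, rng_rnorm(rng, n_velocities, inlet_mean, inlet_sd))
    cdir <- file.path(dir, "cases", id)
    dir.create(cdir, showWarnings = FALSE)
    write_mesh_vtk(mesh, file.path(cdir, "mesh.vtu"))
    write_nifti(pm$image, file.path(cdir, "image.nii.gz"))
    write_nifti(pm$mask, file.path(cdir, "mask.nii.gz"), mask = TRUE)
    for (v in vels) {
      f <- analytic_flow(mesh, v)
      write_mesh_vtk(mesh, file.path(cdir, sprintf("fields_v%.4f.vtu", v)),
                     fields = f)
    }
    sweep_used <- NULL
    if (id %in% split_ids$test) {
      sweep_used <- sweep
      for (v in sweep) {
        f <- analytic_flow(mesh, v)
        write_mesh_vtk(mesh, file.path(cdir, sprintf("fields_v%.4f.vtu", v)),
                       fields = f)
      }
    }
    files <- list.files(cdir)
    hashes <- as.list(tools::md5sum(file.path(cdir, files)))
    names(hashes) <- files
    cases[[id]] <- list(seed = case_seed, params = unclass(params),
                        velocities = vels, sweep = sweep_used, files = hashes)
  }
  manifest <- list(scale = scale, master_seed = master_seed,
                   grid_size = d, spacing = 1.0,
                   resolution = res, n_cases = n_cases,
                   split = split_ids, cases = cases)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset manifest
#' @param dir dataset directory.
#' @return the manifest list.
#' @export
load_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
}

#' Load one case from a dataset directory
#'
#' @param dir dataset directory.
#' @param id case id (e.g. `"case_001"`).
#' @param manifest optional pre-read manifest.
#' @return list with `mesh` (lattice re-attached), `image`, `mask`,
#'   `fields` (named by velocity string), `velocities`, `sweep`.
#' @export
load_case <- function(dir, id, manifest = NULL) {
  if (is.null(manifest)) manifest <- load_manifest(dir)
  info <- manifest$cases[[id]]
  if (is.null(info)) stop("unknown case id: ", id)
  cdir <- file.path(dir, "cases", id)
  mesh <- read_mesh_vtk(file.path(cdir, "mesh.vtu"))$mesh
  res <- do.call(mesh_resolution,
                 c(list(scale = manifest$scale), manifest$resolution[
                   c("rings", "sectors", "trunk_stations", "branch_stations")]))
  mesh <- attach_lattice(mesh, res)
  img <- read_nifti(file.path(cdir, "image.nii.gz"))
  msk <- read_nifti(file.path(cdir, "mask.nii.gz"))
  fieldfiles <- grep("^fields_v", names(info$files), value = TRUE)
  fields <- list()
  for (ff in fieldfiles) {
    v <- sub("^fields_v(.*)\\.vtu$", "\\1", ff)
    fields[[v]] <- read_mesh_vtk(file.path(cdir, ff))$fields
  }
  list(mesh = mesh, image = img, mask = round(msk$voxels),
       fields = fields, velocities = unlist(info$velocities),
       sweep = info$sweep, params = info$params)
}

# centered-difference centerline tangents on the station polylines; shared by
# the mesh builder and attach_lattice so that the analytic flow oracle gives
# identical flow directions whether the lattice is exact or re-fit.
.lattice_tangents <- function(centers, seg_of, st_of, TT, B, branch_row) {
  n_rows <- nrow(centers)
  tangents <- matrix(0, n_rows, 3L)
  for (row in seq_len(n_rows)) {
    seg <- seg_of[row]; s <- st_of[row]
    nxt <- if (seg == 0L) { if (s < TT - 1L) row + 1L else NA
    } else if (s < B) branch_row(seg, s + 1L) else NA
    prv <- if (seg == 0L) { if (s > 0L) row - 1L else NA
    } else if (s > 1L) branch_row(seg, s - 1L) else TT
    a <- if (is.na(prv)) centers[row, ] else centers[prv, ]
    b <- if (is.na(nxt)) centers[row, ] else centers[nxt, ]
    tv <- b - a
    tangents[row, ] <- tv / sqrt(sum(tv^2))
  }
  tangents
}

#' Recover lattice metadata for a mesh with known lattice topology
#'
#' Node ordering on the (segment, station, ring, sector) lattice is implied by
#' the resolution alone; per-station centers, tangents and radii are re-fit
#' from the node positions. Also produces least-squares-style anatomy
#' estimates (radii from mean wall distance, lengths from centerline
#' arclength, half-angles from end-to-junction directions) -- the geometric
#' fit used when running the analytic flow oracle on a predicted mesh.
#'
#' @param mesh a `volume_mesh` whose nodes follow the lattice ordering.
#' @param res the [mesh_resolution()] used to build the topology.
#' @return the mesh with a `lattice` element (including fitted `params`).
#' @export
attach_lattice <- function(mesh, res) {
  R <- res$rings; S <- res$sectors
  TT <- res$trunk_stations; B <- res$branch_stations
  P <- 1L + R * S
  Pint <- P - S
  n_rows <- TT + 2L * B + 1L
  j2_row <- TT + B + 1L
  row_np <- rep(P, n_rows); row_np[j2_row] <- Pint
  row_base <- cumsum(c(0L, row_np))[seq_len(n_rows)]
  if (nrow(mesh$nodes) != sum(row_np))
    stop("node count does not match the lattice resolution")
  branch_row <- function(b, s) if (b == 1L) TT + s else j2_row + s
  seg_of <- integer(n_rows); st_of <- integer(n_rows)
  seg_of[1:TT] <- 0L; st_of[1:TT] <- 0:(TT - 1L)
  seg_of[TT + 1:B] <- 1L; st_of[TT + 1:B] <- 1:B
  seg_of[j2_row] <- 2L; st_of[j2_row] <- 0L
  seg_of[j2_row + 1:B] <- 2L; st_of[j2_row + 1:B] <- 1:B

  centers <- matrix(0, n_rows, 3L)
  radii <- numeric(n_rows)
  for (row in seq_len(n_rows)) {
    idx <- row_base[row] + seq_len(row_np[row])
    if (row == j2_row)  # septum shares the junction wall ring
      idx <- c(idx, row_base[TT] + Pint + seq_len(S))
    centers[row, ] <- colMeans(mesh$nodes[idx, , drop = FALSE])
    wall_base <- if (row == j2_row) row_base[TT] else row_base[row]
    wall <- wall_base + Pint + seq_len(S)
    radii[row] <- mean(sqrt(rowSums(
      sweep(mesh$nodes[wall, , drop = FALSE], 2L, centers[row, ], "-")^2)))
  }
  tangents <- .lattice_tangents(centers, seg_of, st_of, TT, B, branch_row)
  fracs <- ifelse(seg_of == 0L, st_of / (TT - 1L), st_of / B)
  arclen <- function(rows) sum(sqrt(rowSums(
    diff(centers[rows, , drop = FALSE])^2)))
  trunk_rows <- 1:TT
  b1_rows <- c(TT, TT + 1:B); b2_rows <- c(TT, j2_row + 1:B)
  jdir <- centers[TT, ] - centers[1L, ]; jdir <- jdir / sqrt(sum(jdir^2))
  ang <- function(rows) {
    d <- centers[rows[length(rows)], ] - centers[TT, ]
    d <- d / sqrt(sum(d^2))
    acos(pmin(1, pmax(-1, sum(d * jdir)))) * 180 / pi
  }
  late <- function(rows) mean(radii[rows[(length(rows) %/% 2 + 1L):length(rows)]])
  params <- anatomy_params(
    scale = if (nrow(mesh$nodes) <= 2000) "small" else "paper",
    trunk_radius = mean(radii[trunk_rows]),
    trunk_length = arclen(trunk_rows),
    branch_radius = c(late(b1_rows), late(b2_rows)),
    branch_length = c(arclen(b1_rows), arclen(b2_rows)),
    half_angle = c(ang(b1_rows), ang(b2_rows)),
    curve_amp = 0, bump_amp = 0)
  ring_full <- c(0L, rep(1:R, each = S))
  sector_full <- c(0L, rep(0:(S - 1L), R))
  per_row <- function(x) unlist(lapply(seq_len(n_rows), function(r)
    rep(x[r], row_np[r])))
  mesh$lattice <- list(res = res, params = params,
                       node_seg = per_row(seg_of),
                       node_station = per_row(st_of),
                       node_ring = unlist(lapply(row_np, function(np) ring_full[seq_len(np)])),
                       node_sector = unlist(lapply(row_np, function(np) sector_full[seq_len(np)])),
                       station_row = per_row(seq_len(n_rows)),
                       row_base = row_base, row_np = row_np, j2_row = j2_row,
                       centers = centers, tangents = tangents,
                       fracs = fracs, radii = radii,
                       seg_of_row = seg_of, st_of_row = st_of)
  mesh
}
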