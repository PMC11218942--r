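# Shared fixtures, built once per test run. All geometry is generated in
# code; nothing is read from disk except files the tests themselves write
# to tempdir().

.fix <- new.env(parent = emptyenv())

fix_once <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# one regular-ish tet
single_tet_mesh <- function() {
  volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              matrix(c(1, 2, 3, 4), 1))
}

# two tets sharing the face (1,2,3)
two_tet_mesh <- function() {
  volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(0.4, 0.4, -1)),
              rbind(c(1, 2, 3, 4), c(1, 3, 2, 5)))
}

# a regular tetrahedron (equilateral edges)
regular_tet_mesh <- function() {
  s <- 1 / sqrt(2)
  volume_mesh(rbind(c(1, 0, -s), c(-1, 0, -s), c(0, 1, s), c(0, -1, s)),
              matrix(c(1, 2, 4, 3), 1))
}

small_params <- function() anatomy_params("small")

small_mesh <- function() fix_once("small_mesh", function()
  build_structured_tube_mesh(small_params(), center = rep(15.5, 3)))

small_flow <- function(v = 0.2) analytic_flow(small_mesh(), v)

# a coarse lattice mesh for cheap loss/geometry tests
coarse_mesh <- function() fix_once("coarse_mesh", function()
  build_structured_tube_mesh(
    small_params(),
    mesh_resolution("small", rings = 2L, sectors = 8L,
                    trunk_stations = 5L, branch_stations = 3L),
    center = rep(15.5, 3)))

# a tiny dataset on disk, shared across tests that need one
tiny_dataset <- function() fix_once("tiny_dataset", function() {
  dir <- file.path(tempdir(), "hemomesh-tiny-ds")
  if (!file.exists(file.path(dir, "manifest.json")))
    generate_dataset(dir, 5, c(3L, 1L, 1L), master_seed = 101)
  list(dir = dir, manifest = load_manifest(dir))
})

# a tiny model-state over the tiny dataset (cheap config)
tiny_model_config <- function()
  model_config("small", filters = c(2L, 3L, 4L, 5L, 6L), blocks = 1L,
               dropout = 0)

tiny_state <- function() fix_once("tiny_state", function() {
  ds <- tiny_dataset()
  cs <- load_case(ds$dir, "case_001", ds$manifest)
  stats <- fit_stats(cs$fields)
  st <- init_model(cs$mesh, cs$fields[[1]], stats, tiny_model_config(),
                   image_size = 32, seed = 5)
  list(state = st, case = cs, stats = stats)
})

# brute-force oracles ------------------------------------------------------

bf_chamfer <- function(p, g, reduction = "mean") {
  d1 <- apply(p, 1, function(x) min(colSums((t(g) - x)^2)))
  d2 <- apply(g, 1, function(x) min(colSums((t(p) - x)^2)))
  if (reduction == "mean") mean(d1) + mean(d2) else sum(d1) + sum(d2)
}

bf_aspect <- function(mesh) {
  ratios <- apply(mesh$tets, 1, function(tt) {
    v <- mesh$nodes[tt, ]
    lens <- c()
    for (a in 1:3) for (b in (a + 1):4)
      lens <- c(lens, sqrt(sum((v[a, ] - v[b, ])^2)))
    max(lens) / min(lens)
  })
  mean(ratios)
}

bf_laplacian <- function(edges, n) {
  a <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- 1
    a[edges[r, 2], edges[r, 1]] <- 1
  }
  deg <- rowSums(a)
  dm <- diag(ifelse(deg > 0, 1 / sqrt(deg), 0), n)
  l <- diag(n) - dm %*% a %*% dm
  lt <- l - diag(n)                     # lambda_max fixed at 2
  lt[deg == 0, ] <- 0
  for (i in which(deg == 0)) lt[i, i] <- -1
  lt
}

# directional finite-difference derivative of f at x along v
fd_directional <- function(f, x, v, eps = 1e-6) {
  (f(x + eps * v) - f(x - eps * v)) / (2 * eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
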