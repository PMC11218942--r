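test_that("lattice mesh matches the closed-form counts and is valid", {
  res <- mesh_resolution("small", rings = 2L, sectors = 8L,
                         trunk_stations = 5L, branch_stations = 3L)
  m <- build_structured_tube_mesh(small_params(), res, center = rep(15.5, 3))
  lc <- lattice_counts(res)
  expect_equal(nrow(m$nodes), lc$n_nodes)
  expect_equal(nrow(m$tets), lc$n_tets)
  expect_true(all(tet_volumes(m) > 0))
  expect_length(m$cap_faces, 3L)

  # default small lattice: frozen regression values
  md <- small_mesh()
  lcd <- lattice_counts(mesh_resolution("small"))
  expect_equal(nrow(md$nodes), lcd$n_nodes)
  expect_equal(nrow(md$nodes), 641L)
  expect_lt(aspect_ratio_loss(md), 3)
})

test_that("connectivity is identical across anatomy draws (correspondence)", {
  ref <- small_mesh()
  rng <- rng_stream(11)
  for (i in 1:5) {
    p <- sample_anatomy(rng, "small")
    m <- build_structured_tube_mesh(p, center = rep(15.5, 3))
    expect_identical(m$tets, ref$tets)
    expect_identical(m$cap_faces, ref$cap_faces)
    expect_false(isTRUE(all.equal(m$nodes, ref$nodes)))
  }
})

test_that("too-narrow bifurcation angles are rejected", {
  p <- anatomy_params("small", half_angle = c(2, 2))
  expect_error(build_structured_tube_mesh(p), "self-intersect")
})

test_that("analytic flow obeys the Poiseuille physics exactly", {
  m <- small_mesh()
  par <- small_params()
  f <- analytic_flow(m, 0.2)
  fl <- attr(f, "flow")

  # closed form: straight tube r=1mm, L=10mm, v=0.2 m/s
  # dp = 8 mu L Q/(pi r^4) = 8*0.04*0.01*(0.2*pi*1e-6)/(pi*1e-12) = 640 Pa
  q <- 0.2 * pi * 1e-6
  expect_equal(poiseuille_dp(1, 10, q), 640, tolerance = 1e-9)

  # inlet pressure equals the closed-form series resistance sum
  g <- 1 / (8 * 0.04 * (par$branch_length * 1e-3) /
            (pi * (par$branch_radius * 1e-3)^4))
  q_in <- 0.2 * pi * (par$trunk_radius * 1e-3)^2
  p_j <- q_in / sum(g)
  expect_equal(fl$p_junction, p_j, tolerance = 1e-12)
  expect_equal(fl$p_inlet,
               p_j + poiseuille_dp(par$trunk_radius, par$trunk_length, q_in),
               tolerance = 1e-12)

  # exact conservation at the bifurcation
  expect_equal(sum(fl$Q_branch), fl$Q_in, tolerance = 1e-15)

  # outlet gauge pressures exactly zero
  out_idx <- unique(as.vector(rbind(m$cap_faces$outlet_left,
                                    m$cap_faces$outlet_right)))
  expect_true(all(f$pressure[out_idx] == 0))

  # no-slip walls, 2x peak centerline velocity at the inlet disk
  lat <- m$lattice
  wall <- lat$node_ring == lat$res$rings
  expect_true(all(rowSums(f$velocity[wall, ]^2) == 0))
  inlet_center <- which(lat$node_seg == 0 & lat$node_station == 0 &
                        lat$node_ring == 0)
  expect_equal(sqrt(sum(f$velocity[inlet_center, ]^2)), 2 * 0.2,
               tolerance = 1e-12)

  # pressure non-increasing downstream along every segment
  for (seg in 0:2) {
    rows <- which(lat$seg_of_row == seg)
    rows <- rows[order(lat$st_of_row[rows])]
    ps <- sapply(rows, function(r) {
      f$pressure[which(lat$station_row == r)[1]]
    })
    expect_true(all(diff(ps) <= 1e-12))
  }

  # doubling the inlet velocity doubles every field exactly
  f2 <- analytic_flow(m, 0.4)
  expect_equal(f2$pressure, 2 * f$pressure, tolerance = 1e-15)
  expect_equal(f2$velocity, 2 * f$velocity, tolerance = 1e-15)

  expect_error(analytic_flow(m, 0), "positive")
})

test_that("pseudo-MRI rasterization is seeded and contrast-correct", {
  m <- small_mesh()
  clean <- rasterize_pseudo_mri(m, 32, seed = 9, noise_sd = 0,
                                n_blobs = 0L, bias_amp = 0)
  img <- clean$image$voxels
  expect_true(all(img[clean$mask == 1] == 0.8))
  expect_true(all(img[clean$mask == 0] == 0.3))

  a <- rasterize_pseudo_mri(m, 32, seed = 4)
  b <- rasterize_pseudo_mri(m, 32, seed = 4)
  expect_identical(a$image$voxels, b$image$voxels)
  c2 <- rasterize_pseudo_mri(m, 32, seed = 5)
  expect_false(identical(a$image$voxels, c2$image$voxels))

  expect_gt(mean(a$image$voxels[a$mask == 1]),
            mean(a$image$voxels[a$mask == 0]))
  expect_true(all(a$image$voxels >= 0 & a$image$voxels <= 1))
})

test_that("dataset generation: bookkeeping, determinism, velocity stats", {
  ds <- tiny_dataset()
  man <- ds$manifest
  expect_length(man$cases, 5L)
  expect_equal(length(man$split$train), 3L)
  # train case: 4 field sets; test case: 4 + 3-velocity sweep
  tr <- load_case(ds$dir, man$split$train[1], man)
  te <- load_case(ds$dir, man$split$test[1], man)
  expect_length(tr$fields, 4L)
  expect_length(te$fields, 7L)
  expect_equal(te$sweep, c(0.1, 0.2, 0.3))
  # correspondence on disk: tets byte-identical
  expect_identical(tr$mesh$tets, te$mesh$tets)

  # same master seed regenerates identical file hashes
  d2 <- file.path(tempdir(), "hemomesh-tiny-ds-b")
  unlink(d2, recursive = TRUE)
  man2 <- generate_dataset(d2, 5, c(3L, 1L, 1L), master_seed = 101)
  h1 <- unlist(lapply(man$cases, function(x) unlist(x$files)))
  h2 <- unlist(lapply(man2$cases, function(x) unlist(x$files)))
  expect_equal(unname(h1), unname(h2))
  unlink(d2, recursive = TRUE)

  # law of large numbers on the inlet-velocity draws (no disk I/O needed)
  rng <- rng_stream(77)
  v <- rng_rnorm(rng, 4000, 0.2, 0.05)
  expect_lt(abs(mean(v) - 0.2), 0.01)
  expect_lt(abs(sd(v) - 0.05), 0.01)
})

test_that("attach_lattice re-fits geometry that reproduces the flow oracle", {
  ds <- tiny_dataset()
  cs <- load_case(ds$dir, "case_002", ds$manifest)
  truth <- cs$fields[[1]]
  vin <- as.numeric(names(cs$fields)[1])
  refit <- analytic_flow(cs$mesh, vin)
  expect_lt(max(abs(refit$pressure - truth$pressure)) / max(truth$pressure),
            0.01)
  expect_lt(max(abs(refit$velocity - truth$velocity)) /
            max(abs(truth$velocity)), 0.01)
})
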