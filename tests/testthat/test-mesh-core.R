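test_that("extract_edges enumerates and deduplicates tet edges", {
  m1 <- single_tet_mesh()
  e1 <- extract_edges(m1)
  expect_equal(e1, cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4)))

  m2 <- two_tet_mesh()
  e2 <- extract_edges(m2)
  expect_equal(nrow(e2), 9L)                       # 12 raw, 3 shared
  expect_true(all(e2[, 1] < e2[, 2]))
  expect_false(any(duplicated(paste(e2[, 1], e2[, 2]))))

  empty <- volume_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 4))
  expect_equal(nrow(extract_edges(empty)), 0L)

  bad <- volume_mesh(matrix(rnorm(12), 4, 3), matrix(c(1, 1, 2, 3), 1),
                     validate = FALSE)
  expect_error(extract_edges(bad), "degenerate")
})

test_that("extract_surface keeps multiplicity-1 faces, outward oriented", {
  s1 <- extract_surface(single_tet_mesh())
  expect_equal(nrow(s1$triangles), 4L)

  m2 <- two_tet_mesh()
  s2 <- extract_surface(m2)
  expect_equal(nrow(s2$triangles), 6L)             # shared face absent
  shared <- apply(s2$triangles, 1, function(t) setequal(t, c(1, 2, 3)))
  expect_false(any(shared))
  expect_equal(nrow(s2$edges), 9L)                 # closed 2-tet surface

  # outward orientation: normals point away from the mesh centroid
  cen <- colMeans(m2$nodes)
  n <- face_normals(m2, s2$triangles)
  mid <- t(apply(s2$triangles, 1, function(t) colMeans(m2$nodes[t, ])))
  expect_true(all(rowSums(n * sweep(mid, 2, cen)) > -1e-9))

  # watertightness of a convex mesh: every surface edge borders 2 triangles
  e <- rbind(s2$triangles[, c(1, 2)], s2$triangles[, c(2, 3)],
             s2$triangles[, c(3, 1)])
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(k) == 2L))

  # non-manifold: three tets stacked on one face
  bad <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                           c(0, 0, -1), c(0.5, 0.5, 1)),
                     rbind(c(1, 2, 3, 4), c(1, 3, 2, 5), c(1, 2, 3, 6)),
                     validate = FALSE)
  expect_error(extract_surface(bad), "non-manifold")
})

test_that("face_normals are unit, orientation-sensitive, cross-product exact", {
  m <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   matrix(c(1, 2, 3, 4), 1))
  expect_equal(as.numeric(face_normals(m, rbind(c(1, 2, 3)))), c(0, 0, 1))
  expect_equal(as.numeric(face_normals(m, rbind(c(1, 3, 2)))), c(0, 0, -1))
  expect_equal(as.numeric(face_normals(m, rbind(c(1, 2, 4)))), c(0, -1, 0))
  n <- face_normals(m, rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(rowSums(n^2), c(1, 1), tolerance = 1e-12)
  degen <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 1)),
                       matrix(c(1, 2, 3, 4), 1), validate = FALSE)
  expect_error(face_normals(degen, rbind(c(1, 2, 3))), "zero-area")
})

test_that("scaled_laplacian matches the dense brute-force construction", {
  # two nodes, one edge: exact hand value
  m <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   matrix(c(1, 2, 3, 4), 1))
  lt <- scaled_laplacian(m)
  dense <- bf_laplacian(extract_edges(m), 4L)
  expect_lt(max(abs(as.matrix(lt) - dense)), 1e-12)

  # a 2-node graph via explicit edges
  m2 <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), matrix(integer(0), 0, 4))
  lt2 <- scaled_laplacian(m2, edges = cbind(1L, 2L))
  expect_equal(as.matrix(lt2), rbind(c(0, -1), c(-1, 0)),
               ignore_attr = TRUE)

  # random small meshes vs dense oracle; symmetry; eigenvalues in [-1, 1]
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    edges <- t(combn(n, 2))
    edges <- edges[runif(nrow(edges)) < 0.4, , drop = FALSE]
    mm <- volume_mesh(matrix(rnorm(3 * n), n, 3), matrix(integer(0), 0, 4))
    lt <- suppressWarnings(scaled_laplacian(mm, edges = edges))
    dense <- bf_laplacian(edges, n)
    expect_lt(max(abs(as.matrix(lt) - dense)), 1e-12)
    expect_lt(max(abs(as.matrix(lt) - t(as.matrix(lt)))), 1e-12)
    ev <- eigen(dense, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
  # isolated node warns and gets a -1 diagonal
  expect_warning(lt3 <- scaled_laplacian(m2, edges = matrix(integer(0), 0, 2)))
  expect_equal(Matrix::diag(lt3), c(-1, -1))
})

test_that("voxelize rasterizes by barycentric inclusion", {
  big <- volume_mesh(20 * rbind(c(-1, -1, -1), c(3, 0, 0), c(0, 3, 0),
                                c(0, 0, 3)),
                     matrix(c(1, 2, 3, 4), 1))
  mask <- suppressWarnings(voxelize(big, 8L))  # big tet exceeds the grid
  expect_equal(mask[1, 1, 1], 1L)   # voxel center (0,0,0) inside

  outside <- volume_mesh(rbind(c(100, 100, 100), c(101, 100, 100),
                               c(100, 101, 100), c(100, 100, 101)),
                         matrix(c(1, 2, 3, 4), 1))
  expect_warning(m0 <- voxelize(outside, 8L), "clipped")
  expect_true(all(m0 == 0L))

  degen <- volume_mesh(matrix(0, 4, 3), matrix(c(1, 2, 3, 4), 1),
                       validate = FALSE)
  expect_warning(mz <- voxelize(degen, 4L), "zero-volume")
  expect_true(all(mz == 0L))

  # axis-aligned tube of radius 4 voxels vs analytic cylinder volume
  r <- 4; len <- 20
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ring <- cbind(cos(th), sin(th))
  nodes <- rbind(c(0, 0, 0), c(0, 0, len))
  for (z in c(0, len)) nodes <- rbind(nodes, cbind(16 + r * ring, z))
  nodes[1:2, 1:2] <- 16
  tets <- NULL
  for (j in 1:32) {
    jn <- j %% 32 + 1
    a <- 2 + j; b <- 2 + jn; a2 <- 34 + j; b2 <- 34 + jn
    tets <- rbind(tets, c(1, a, b, a2), c(1, b, b2, a2), c(1, b2, 2, a2))
  }
  tube <- volume_mesh(nodes, tets, validate = FALSE)
  mask <- voxelize(tube, 32L)
  analytic <- pi * r^2 * len
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.05)
})

test_that("trilinear sampling is exact where trilinearity promises it", {
  # voxel centers and midpoints
  g <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  v <- sample_image_features(g, rbind(c(1, 2, 3)))
  expect_equal(as.numeric(v), g[2, 3, 4, ], tolerance = 1e-12)
  mid <- sample_image_features(g, rbind(c(1.5, 2, 3)))
  expect_equal(as.numeric(mid), (g[2, 3, 4, ] + g[3, 3, 4, ]) / 2,
               tolerance = 1e-12)

  # exact reproduction of a trilinear polynomial field
  ax <- 0:7
  f <- outer(outer(2 * ax, 3 * ax, "+"), -ax, "+")   # 2x + 3y - z
  set.seed(7)
  pts <- cbind(runif(50, 0, 7), runif(50, 0, 7), runif(50, 0, 7))
  got <- sample_image_features(array(f, c(8, 8, 8, 1)), pts)
  want <- 2 * pts[, 1] + 3 * pts[, 2] - pts[, 3]
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)

  # out-of-bounds clamps to the boundary voxel
  edge <- sample_image_features(array(f, c(8, 8, 8, 1)), rbind(c(-3, 0, 0)))
  expect_equal(as.numeric(edge), f[1, 1, 1], tolerance = 1e-12)
  expect_error(sample_image_features(g, rbind(c(NA, 1, 1))), "non-finite")
})

test_that("mesh validation catches the invariant violations", {
  expect_error(volume_mesh(matrix(0, 3, 3), matrix(c(1, 2, 3, 4), 1)),
               "out of range")
  expect_error(volume_mesh(matrix(rnorm(12), 4, 3),
                           matrix(c(1, 1, 2, 3), 1)), "degenerate")
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(volume_mesh(flat, matrix(1:4, 1)), "volume")
  expect_error(field_set(c(1, NA), matrix(0, 2, 3)), "finite")
  expect_error(field_set(1, matrix(0, 2, 3)))
})
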