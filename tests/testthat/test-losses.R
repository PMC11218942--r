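test_that("chamfer loss: identity, hand value, brute-force oracle, scaling", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(chamfer_loss(p, p), 0)
  expect_equal(chamfer_loss(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1)), 2)
  for (rep in 1:5) {
    a <- matrix(rnorm(3 * sample(5:50, 1)), ncol = 3)
    b <- matrix(rnorm(3 * sample(5:50, 1)), ncol = 3)
    expect_equal(chamfer_loss(a, b), bf_chamfer(a, b), tolerance = 1e-12)
    expect_equal(chamfer_loss(a, b, "sum"), bf_chamfer(a, b, "sum"),
                 tolerance = 1e-12)
    expect_equal(chamfer_loss(a, b), chamfer_loss(b, a))      # symmetry
    s <- 2.5                                                   # x s^2 scaling
    expect_equal(chamfer_loss(s * a, s * b), s^2 * chamfer_loss(a, b),
                 tolerance = 1e-9)
  }
  expect_error(chamfer_loss(matrix(0, 0, 3), p), "non-empty")
})

test_that("edge-deviation loss: hand values and scale invariance", {
  expect_equal(edge_deviation_loss(rep(2, 10)), 0)
  expect_equal(edge_deviation_loss(c(1, 3)), 0.5)      # population sd 1, mean 2
  expect_equal(edge_deviation_loss(c(10, 30)), 0.5)    # scale invariant
  set.seed(2)
  x <- runif(40, 0.5, 2)
  expect_equal(edge_deviation_loss(3 * x), edge_deviation_loss(x),
               tolerance = 1e-12)
  expect_error(edge_deviation_loss(c(1, 0)), "zero-length")
  expect_error(edge_deviation_loss(1), "at least 2")
})

test_that("aspect-ratio loss: equilateral floor, hand value, oracle", {
  expect_equal(aspect_ratio_loss(regular_tet_mesh()), 1, tolerance = 1e-12)
  skew <- volume_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      matrix(1:4, 1))
  expect_equal(aspect_ratio_loss(skew), sqrt(5), tolerance = 1e-12)
  m <- coarse_mesh()
  expect_equal(aspect_ratio_loss(m), bf_aspect(m), tolerance = 1e-9)
  expect_gte(aspect_ratio_loss(m), 1)
  # scale invariance
  m2 <- volume_mesh(3 * m$nodes, m$tets)
  expect_equal(aspect_ratio_loss(m2), aspect_ratio_loss(m), tolerance = 1e-9)
})

test_that("cap-coplanar loss: flat caps, hand value, rigid invariance", {
  m <- small_mesh()
  expect_lt(cap_coplanar_loss(m), 1e-20)   # lattice caps are flat

  # two-face cap with normals (0,0,1) and (1,0,0): hand value 1.0
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),      # +z triangle
                 c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))      # +x triangle
  fake <- list(nodes = nodes, tets = matrix(integer(0), 0, 4),
               cap_faces = list(inlet = rbind(c(1, 2, 3), c(4, 5, 6)),
                                outlet_left = rbind(c(1, 2, 3)),
                                outlet_right = rbind(c(4, 5, 6))))
  class(fake) <- "volume_mesh"
  # inlet term: deviations each 0.5 -> 1.0; single-face caps contribute 0
  expect_equal(cap_coplanar_loss(fake), 1.0, tolerance = 1e-12)

  # rigid rotation + translation leaves the loss unchanged
  th <- pi / 2
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fake2 <- fake
  fake2$nodes <- sweep(nodes %*% t(rot), 2, c(3, -1, 2), "+")
  expect_equal(cap_coplanar_loss(fake2), cap_coplanar_loss(fake),
               tolerance = 1e-9)

  m2 <- m; m2$cap_faces$inlet <- NULL
  expect_error(cap_coplanar_loss(m2), "missing cap")
})

test_that("cfd loss: identity, offset, brute-force oracle", {
  set.seed(3)
  a <- matrix(rnorm(40), 10, 4)
  expect_equal(cfd_loss(a, a), 0)
  expect_equal(cfd_loss(a + 1, a), 4)      # 4 channels x MAE 1
  b <- matrix(rnorm(40), 10, 4)
  bf <- 0
  for (ch in 1:4) {
    s <- 0
    for (j in 1:10) s <- s + abs(a[j, ch] - b[j, ch])
    bf <- bf + s / 10
  }
  expect_equal(cfd_loss(a, b), bf, tolerance = 1e-12)
  expect_error(cfd_loss(a, b[1:5, ]), "mismatch")
})

test_that("branch and total loss compose the verified sub-terms", {
  m <- coarse_mesh()
  f <- analytic_flow(m, 0.2)
  stats <- fit_stats(list(f))
  fs <- standardize_fields(f, stats)
  pred <- list(mesh = m, fields = fs)
  truth <- list(mesh = m, fields = fs)
  w <- loss_weights()
  r <- branch_mesh_loss(pred, truth, w)
  # identity: all terms 0 except the mesh-quality floors
  expect_equal(r$point, 0); expect_equal(r$cfd, 0); expect_equal(r$cap, 0,
                                                                 tolerance = 1e-18)
  expect_equal(r$mesh_loss,
               w$lambda2 * (r$edge + r$edge_surface) +
               w$lambda3 * aspect_ratio_loss(m),
               tolerance = 1e-9)

  # zero weights kill everything
  z <- loss_weights(0, 0, 0, 0, 0)
  expect_equal(branch_mesh_loss(pred, truth, z)$mesh_loss, 0)

  # a perturbed prediction: weighted sum equals the individually computed terms
  set.seed(4)
  m2 <- volume_mesh(m$nodes + 0.05 * matrix(rnorm(length(m$nodes)),
                                            ncol = 3), m$tets, m$cap_faces,
                    validate = FALSE)
  pred2 <- list(mesh = m2, fields = fs + 0.1)
  r2 <- branch_mesh_loss(pred2, truth, w)
  expect_equal(r2$mesh_loss,
               w$lambda1 * (r2$point + r2$point_surface) +
               w$lambda2 * (r2$edge + r2$edge_surface) +
               w$lambda3 * r2$aspect + w$lambda4 * r2$cap +
               w$lambda5 * r2$cfd, tolerance = 1e-12)

  # total loss: additivity over 3 branches
  tot <- total_loss(list(pred2, pred2, pred2), truth, w)
  expect_equal(tot$total, 3 * r2$mesh_loss, tolerance = 1e-9)
  tot2 <- total_loss(list(pred, pred2, pred), truth, w)
  expect_equal(tot2$total, 2 * r$mesh_loss + r2$mesh_loss, tolerance = 1e-9)
  expect_error(total_loss(list(pred, pred2), truth, w), "3 branch")
  expect_error(loss_weights(lambda1 = -1), "non-negative")
})

test_that("tape losses agree with the numeric implementations", {
  m <- coarse_mesh()
  topo <- loss_topology(m)
  set.seed(5)
  x <- m$nodes + 0.03 * matrix(rnorm(length(m$nodes)), ncol = 3)
  tgt <- m$nodes
  tape <- ad_tape()
  xn <- ad_input(tape, x)
  expect_equal(tape_chamfer(tape, xn, tgt)$value, chamfer_loss(x, tgt),
               tolerance = 1e-12)
  expect_equal(tape_edge_deviation(tape, xn, topo$edges)$value,
               edge_deviation_loss(
                 sqrt(rowSums((x[topo$edges[, 1], ] - x[topo$edges[, 2], ])^2))),
               tolerance = 1e-12)
  mx <- volume_mesh(x, m$tets, m$cap_faces, validate = FALSE)
  expect_equal(tape_aspect(tape, xn, topo$tets)$value, aspect_ratio_loss(mx),
               tolerance = 1e-12)
  expect_equal(tape_cap(tape, xn, topo$cap_faces)$value,
               cap_coplanar_loss(mx), tolerance = 1e-12)
})

test_that("each loss term passes a finite-difference gradient check", {
  m <- coarse_mesh()
  topo <- loss_topology(m)
  set.seed(6)
  x0 <- m$nodes + 0.05 * matrix(rnorm(length(m$nodes)), ncol = 3)
  tgt <- m$nodes + 0.02 * matrix(rnorm(length(m$nodes)), ncol = 3)
  f0 <- matrix(rnorm(nrow(x0) * 4), ncol = 4)
  ft <- matrix(rnorm(nrow(x0) * 4), ncol = 4)

  terms <- list(
    chamfer = function(tape, xn) tape_chamfer(tape, xn, tgt),
    edge = function(tape, xn) tape_edge_deviation(tape, xn, topo$edges),
    aspect = function(tape, xn) tape_aspect(tape, xn, topo$tets),
    cap = function(tape, xn) tape_cap(tape, xn, topo$cap_faces))
  for (nm in names(terms)) {
    tape <- ad_tape()
    xn <- ad_input(tape, x0)
    loss <- terms[[nm]](tape, xn)
    ad_backward(tape, loss)
    g <- xn$grad
    v <- g / sqrt(sum(g^2))
    fd <- fd_directional(function(x) {
      t2 <- ad_tape()
      terms[[nm]](t2, ad_input(t2, x))$value
    }, x0, v)
    expect_equal(sum(g * v), fd, tolerance = 1e-3, label = nm)
  }
  # cfd term w.r.t. the field matrix
  tape <- ad_tape()
  fn <- ad_input(tape, f0)
  ad_backward(tape, tape_cfd(tape, fn, ft))
  g <- fn$grad
  v <- g / sqrt(sum(g^2))
  fd <- fd_directional(function(f) {
    t2 <- ad_tape()
    tape_cfd(t2, ad_input(t2, f), ft)$value
  }, f0, v)
  expect_equal(sum(g * v), fd, tolerance = 1e-3)
})

test_that("identity prediction on an equilateral tet costs exactly lambda3", {
  m <- regular_tet_mesh()
  m$cap_faces <- list(inlet = rbind(c(1, 2, 3)),
                      outlet_left = rbind(c(1, 2, 4)),
                      outlet_right = rbind(c(2, 3, 4)))
  f <- matrix(rnorm(16), 4, 4)
  r <- branch_mesh_loss(list(mesh = m, fields = f),
                        list(mesh = m, fields = f), loss_weights())
  expect_equal(r$mesh_loss, 0.5 * 1.0, tolerance = 1e-9)
})
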