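test_that("dice: identities and hand value", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1L          # 8 voxels
  b <- array(0L, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1L          # 8, overlap 4
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), dice(b, a))                         # symmetric
  expect_equal(dice(a, b), 0.5)                                # 2*4/16
  d <- array(0L, c(4, 4, 4)); d[4, 4, 4] <- 1L
  expect_equal(dice(a, d), 0)
  expect_warning(v <- dice(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))),
                 "empty")
  expect_equal(v, 1)
  expect_error(dice(a, array(0L, c(2, 2, 2))), "mismatch")
})

# two parallel triangulated unit squares offset by d in z
.parallel_plates <- function(offset) {
  sq <- function(z) rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z))
  mk <- function(z) {
    nodes <- rbind(sq(z), c(0.5, 0.5, z + 0.01))  # shallow tet roof
    volume_mesh(nodes, rbind(c(1, 2, 3, 5), c(1, 3, 4, 5)), validate = FALSE)
  }
  list(a = mk(0), b = mk(offset))
}

test_that("assd and hausdorff: identities, parallel planes, ordering", {
  m <- coarse_mesh()
  expect_equal(assd(m, m), 0, tolerance = 1e-12)
  expect_equal(hausdorff(m, m), 0, tolerance = 1e-12)

  pl <- .parallel_plates(2.5)
  expect_equal(assd(pl$a, pl$b), 2.5, tolerance = 0.02)
  expect_equal(hausdorff(pl$a, pl$b), 2.5, tolerance = 0.02)
  expect_equal(assd(pl$a, pl$b), assd(pl$b, pl$a))

  set.seed(9)
  m2 <- volume_mesh(m$nodes + 0.1 * matrix(rnorm(length(m$nodes)), ncol = 3),
                    m$tets, validate = FALSE)
  expect_gte(hausdorff(m, m2), assd(m, m2))
  expect_gte(hausdorff(m, m2), hausdorff(m, m2, percentile = 95))
})

test_that("NAE: zeros, hand values, invariances", {
  set.seed(10)
  n <- 20
  truth <- field_set(seq(0, 10, length.out = n), matrix(rnorm(3 * n), n, 3))
  expect_true(all(nae(truth, truth) == 0))

  pred <- truth
  pred$pressure[5] <- truth$pressure[5] + 1
  nm <- nae(pred, truth)
  expect_equal(unname(nm[5, "pressure"]), 10)            # 1 / range 10 -> 10%
  expect_true(all(nm[-5, "pressure"] == 0))

  # uniform offset on a channel -> constant NAE = 100 c / range
  pred2 <- truth
  pred2$pressure <- truth$pressure + 2
  expect_equal(nae(pred2, truth)[, "pressure"], rep(20, n),
               tolerance = 1e-9, ignore_attr = TRUE)

  # adding a constant to BOTH leaves NAE unchanged
  both <- function(f, c) field_set(f$pressure + c, f$velocity)
  expect_equal(nae(both(pred2, 5), both(truth, 5)), nae(pred2, truth),
               tolerance = 1e-9)

  # doubling the truth range halves the percentage at fixed absolute error
  truth2 <- field_set(seq(0, 20, length.out = n), truth$velocity)
  pred3 <- field_set(truth2$pressure + 2, truth$velocity)
  expect_equal(nae(pred3, truth2)[, "pressure"], rep(10, n),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(nae(field_set(rep(1, n), truth$velocity),
                   field_set(rep(1, n), truth$velocity)), "zero range")
})

test_that("MNAE_s / MNAE_n and the grand-mean identity", {
  expect_equal(unname(mnae_subject(cbind(pressure = c(10, 20), vmag = c(0, 0),
                                         vx = c(0, 0), vy = c(0, 0),
                                         vz = c(0, 0)))[1]), 15)
  set.seed(11)
  mats <- lapply(1:4, function(i) matrix(runif(50 * 5, 0, 30), 50, 5))
  mn <- mnae_node(mats)
  expect_equal(mn, (mats[[1]] + mats[[2]] + mats[[3]] + mats[[4]]) / 4)
  expect_equal(mnae_node(mats[1]), mats[[1]])
  # grand mean: mean over nodes of MNAE_n == mean over cases of MNAE_s
  expect_equal(colMeans(mn),
               colMeans(do.call(rbind, lapply(mats, function(m)
                 mnae_subject(m)))), tolerance = 1e-12)
  expect_error(mnae_node(list()), "no cases")
})

test_that("bland_altman: trivial cases and oracle", {
  x <- rnorm(10)
  r0 <- bland_altman(x, x)
  expect_equal(r0$bias, 0)
  expect_equal(unname(r0$loa), c(0, 0))
  r2 <- bland_altman(x + 2, x)
  expect_equal(r2$bias, 2)
  expect_equal(unname(r2$loa), c(2, 2))
  set.seed(12)
  p <- rnorm(100); t <- rnorm(100)
  r <- bland_altman(p, t)
  d <- p - t
  expect_equal(r$bias, mean(d))
  expect_equal(unname(r$loa),
               mean(d) + c(-1.96, 1.96) * sqrt(mean((d - mean(d))^2)),
               tolerance = 1e-12)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("error decomposition separates geometry from flow error", {
  ds <- tiny_dataset()
  cs <- load_case(ds$dir, "case_003", ds$manifest)
  vin <- as.numeric(names(cs$fields)[1])
  truth <- cs$fields[[1]]
  res <- do.call(mesh_resolution,
                 c(list(scale = "small"), ds$manifest$resolution[
                   c("rings", "sectors", "trunk_stations", "branch_stations")]))

  # perfect geometry and perfect fields: both MNAE ~ 0 (the oracle re-fit
  # reproduces the generating flow to < 1% on its own lattice)
  r <- error_decomposition(cs$mesh, truth, truth, vin, res)
  expect_true(all(r$mnae_direct == 0))
  expect_true(all(r$mnae_oracle < 1))
  expect_true(all(abs(r$delta) < 1))

  # perfect fields on imperfect geometry: delta <= 0 by construction
  set.seed(13)
  warped <- volume_mesh(cs$mesh$nodes * 1.06, cs$mesh$tets,
                        cs$mesh$cap_faces, validate = FALSE)
  r2 <- error_decomposition(warped, truth, truth, vin, res)
  expect_true(all(r2$delta <= 0))
  expect_true(all(r2$mnae_oracle >= r2$mnae_direct))
})
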