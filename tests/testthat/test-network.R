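test_that("graph convolution: linear-map reduction and operator term", {
  # W1 = 0: per-node linear map X W0
  n <- 4
  x <- matrix(rnorm(n * 2), n, 2)
  w0 <- matrix(rnorm(4), 2, 2)
  lap2 <- scaled_laplacian(
    volume_mesh(matrix(rnorm(6), 2, 3), matrix(integer(0), 0, 4)),
    edges = cbind(1L, 2L))
  tape <- ad_tape()
  out <- hemomesh:::.graph_conv(tape, lap2, ad_input(tape, x[1:2, ]),
                                ad_input(tape, w0),
                                ad_input(tape, matrix(0, 2, 2)),
                                ad_input(tape, numeric(2)))
  expect_equal(out$value, x[1:2, ] %*% w0, tolerance = 1e-12)

  # W0 = 0, W1 = I on the 2-node/1-edge graph: output = Ltilde X
  tape <- ad_tape()
  x2 <- matrix(rnorm(4), 2, 2)
  out2 <- hemomesh:::.graph_conv(tape, lap2, ad_input(tape, x2),
                                 ad_input(tape, matrix(0, 2, 2)),
                                 ad_input(tape, diag(2)),
                                 ad_input(tape, numeric(2)))
  expect_equal(out2$value, rbind(c(0, -1), c(-1, 0)) %*% x2,
               tolerance = 1e-12)
})

test_that("graph convolution is node-permutation equivariant", {
  m <- coarse_mesh()
  lap <- scaled_laplacian(m)
  n <- nrow(m$nodes)
  set.seed(20)
  x <- matrix(rnorm(n * 3), n, 3)
  w0 <- matrix(rnorm(9), 3, 3); w1 <- matrix(rnorm(9), 3, 3)
  b <- rnorm(3)
  gc <- function(lapm, xm) {
    tape <- ad_tape()
    hemomesh:::.graph_conv(tape, lapm, ad_input(tape, xm),
                           ad_input(tape, w0), ad_input(tape, w1),
                           ad_input(tape, b))$value
  }
  perm <- sample(n)
  pm <- Matrix::sparseMatrix(i = seq_len(n), j = perm, x = 1,
                             dims = c(n, n))
  lap_p <- pm %*% lap %*% Matrix::t(pm)
  expect_equal(gc(lap_p, x[perm, ]), gc(lap, x)[perm, ], tolerance = 1e-9)
})

test_that("encoder produces the promised feature pyramid", {
  ts <- tiny_state()
  cfg <- ts$state$config
  fw <- model_forward(ts$state, ts$case$image, 0.2)
  for (l in 1:5) {
    d <- dim(fw$features[[l]]$value)
    expect_equal(d[1:3], rep(32 / 2^(l - 1), 3))
    expect_equal(d[4], cfg$filters[l])
  }
  expect_error(model_config("small", filters = c(8, 8, 16, 32, 64)),
               "strictly increasing")
  cs <- ts$case
  img_bad <- image_volume(array(0, rep(24, 3)))
  expect_error(init_model(cs$mesh, cs$fields[[1]], ts$stats,
                          tiny_model_config(), image_size = 24),
               "divisible")
  expect_error(model_forward(ts$state, img_bad, 0.2), "match")
})

test_that("zero-initialized branches give the identity transform", {
  ts <- tiny_state()
  fw <- model_forward(ts$state, ts$case$image, 0.2)
  for (i in 1:3) {
    expect_equal(fw$branches[[i]]$coords$value, ts$case$mesh$nodes,
                 ignore_attr = TRUE)
    expect_equal(fw$branches[[i]]$fields$value,
                 ts$state$template$fields_std, ignore_attr = TRUE)
  }
  # topology is untouched by construction: predict returns the template tets
  pr <- predict_mesh(ts$state, ts$case$image, 0.2)
  expect_identical(pr$mesh$tets, ts$case$mesh$tets)
  expect_equal(nrow(pr$mesh$nodes), nrow(ts$case$mesh$nodes))
})

test_that("inlet velocity is broadcast to every node and conditions the run", {
  ts <- tiny_state()
  st <- ts$state
  # randomize the bottleneck so outputs respond to inputs
  rng <- rng_stream(31)
  for (nm in grep("out\\.(W0|W1)$", names(st$params), value = TRUE))
    st$params[[nm]] <- matrix(rng_rnorm(rng, length(st$params[[nm]]), 0, 0.05),
                              nrow(st$params[[nm]]))
  p1 <- predict_mesh(st, ts$case$image, 0.1)
  p2 <- predict_mesh(st, ts$case$image, 0.3)
  expect_false(isTRUE(all.equal(p1$mesh$nodes, p2$mesh$nodes)))
  # determinism of inference
  p1b <- predict_mesh(st, ts$case$image, 0.1)
  expect_identical(p1$mesh$nodes, p1b$mesh$nodes)
  expect_identical(p1$fields$pressure, p1b$fields$pressure)
})

test_that("total_loss o forward has correct gradients (tiny model)", {
  ts <- tiny_state()
  st <- ts$state
  rng <- rng_stream(99)
  for (nm in grep("out\\.(W0|W1|b)$", names(st$params), value = TRUE)) {
    p <- st$params[[nm]]
    st$params[[nm]] <- array(rng_rnorm(rng, length(p), 0, 0.01),
                             if (is.null(dim(p))) length(p) else dim(p))
  }
  truth <- list(nodes = ts$case$mesh$nodes,
                fields_mat = standardize_fields(ts$case$fields[[1]], ts$stats))
  lossfun <- function(state) {
    fw <- model_forward(state, ts$case$image, 0.2)
    tl <- hemomesh:::.tape_total_loss(fw$tape, fw, truth, loss_weights(),
                                      state$topo)
    list(fw = fw, tl = tl)
  }
  r <- lossfun(st)
  expect_true(is.finite(r$tl$node$value))
  ad_backward(r$fw$tape, r$tl$node)
  # every parameter grad exists and is finite
  grads <- lapply(r$fw$params, function(p) p$grad)
  expect_true(all(vapply(grads, function(g) is.null(g) || all(is.finite(g)),
                         TRUE)))

  # directional finite-difference check on a sample of tensors
  set.seed(33)
  tensors <- c("enc.L1.B1.conv1.W", "br1.RB1.gc1.W0", "br3.out.W0",
               "br2.adapt.W1", "enc.L2.B1.in1.gamma")
  for (nm in tensors) {
    g <- grads[[nm]]
    v <- array(rnorm(length(g)), dim(g) %||% length(g))
    v <- v / sqrt(sum(v^2))
    eps <- 1e-5
    s2 <- st; s2$params[[nm]] <- st$params[[nm]] + eps * v
    lp <- lossfun(s2)$tl$node$value
    s2$params[[nm]] <- st$params[[nm]] - eps * v
    lm <- lossfun(s2)$tl$node$value
    fd <- (lp - lm) / (2 * eps)
    expect_equal(sum(g * v), fd, tolerance = 1e-3, label = nm)
  }
})
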