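# The hybrid architecture: a five-level residual 3D image encoder and a
# three-branch graph-convolutional template transformer conditioned on a
# scalar inlet velocity. Branch outputs are additive 7-channel deltas
# (x, y, z, pressure, vx, vy, vz) on the running mesh state, so zero-init
# bottlenecks make the untrained network the identity on the template.

#' Model configuration
#'
#' @param scale `"paper"` (128^3 input, encoder filters 16/48/96/192/384) or
#'   `"small"` (32^3 input, filters 8/16/32/64/128, CPU-sized).
#' @param filters encoder filter counts per level (strictly increasing).
#' @param blocks convolutional residual blocks per encoder level.
#' @param dropout spatial dropout rate (training only).
#' @param slope LeakyReLU negative slope.
#' @param branch_levels list of 3 integer pairs: the two encoder levels whose
#'   features each branch samples (coarse-to-fine by default).
#' @param branch_width graph hidden width per branch; defaults to the finer
#'   paired level's channel count.
#' @param initial_width width of the initial graph convolution on template
#'   coordinates + inlet velocity.
#' @return a `model_config`.
#' @export
model_config <- function(scale = c("small", "paper"), filters = NULL,
                         blocks = 2L, dropout = 0.1, slope = 0.2,
                         branch_levels = list(c(5L, 4L), c(4L, 3L), c(3L, 2L)),
                         branch_width = NULL, initial_width = NULL) {
  scale <- match.arg(scale)
  filters <- filters %||% if (scale == "small") c(8L, 16L, 32L, 64L, 128L)
                          else c(16L, 48L, 96L, 192L, 384L)
  if (any(diff(filters) <= 0)) stop("encoder filters must be strictly increasing")
  if (length(branch_levels) != 3L) stop("exactly 3 branches are required")
  levels <- length(filters)
  for (bl in branch_levels)
    if (any(bl < 1L | bl > levels)) stop("branch references a missing encoder level")
  branch_width <- branch_width %||% vapply(branch_levels, function(bl)
    filters[min(bl)], 1L)
  structure(list(scale = scale, filters = as.integer(filters),
                 levels = levels, blocks = as.integer(blocks),
                 dropout = dropout, slope = slope,
                 branch_levels = branch_levels,
                 branch_width = as.integer(branch_width),
                 initial_width = as.integer(initial_width %||% filters[2])),
            class = "model_config")
}

# parameter initialization -----------------------------------------------

.he_sd <- function(fan_in) sqrt(2 / fan_in)

.init_conv <- function(rng, cin, cout, k = 3L) {
  w <- array(rng_rnorm(rng, k^3 * cin * cout, 0, .he_sd(k^3 * cin)),
             c(k, k, k, cin, cout))
  list(W = w, b = numeric(cout))
}

.init_gc <- function(rng, fin, fout, zero = FALSE) {
  if (zero) {
    list(W0 = matrix(0, fin, fout), W1 = matrix(0, fin, fout),
         b = numeric(fout))
  } else {
    sd <- .he_sd(2 * fin)
    list(W0 = matrix(rng_rnorm(rng, fin * fout, 0, sd), fin, fout),
         W1 = matrix(rng_rnorm(rng, fin * fout, 0, sd), fin, fout),
         b = numeric(fout))
  }
}

.init_in <- function(c) list(gamma = rep(1, c), beta = numeric(c))

#' Initialize a model state
#'
#' @param template a `volume_mesh` (the average-anatomy template); its graph
#'   operator, loss topology and standardized template fields are frozen into
#'   the state.
#' @param template_fields a `field_set` on the template (physical units);
#'   used as the starting point of the field channels.
#' @param stats `field_stats` from the training split.
#' @param config a [model_config()].
#' @param image_size input edge length in voxels (must be divisible by
#'   `2^(levels-1)`).
#' @param spacing image spacing, mm.
#' @param seed weight-init seed.
#' @return a `model_state` (parameters, config, template context).
#' @export
init_model <- function(template, template_fields, stats,
                       config = model_config(), image_size, spacing = 1.0,
                       seed = 1L) {
  if (image_size %% 2^(config$levels - 1L) != 0L)
    stop(sprintf("image size %d not divisible by %d: pad or crop the input",
                 image_size, 2^(config$levels - 1L)))
  rng <- rng_stream(seed)
  pars <- list()
  cin <- 1L
  for (l in seq_len(config$levels)) {
    cout <- config$filters[l]
    for (b in seq_len(config$blocks)) {
      bc_in <- if (b == 1L) cin else cout
      for (k in 1:3) {
        kin <- if (k == 1L) bc_in else cout
        pars[[sprintf("enc.L%d.B%d.conv%d", l, b, k)]] <- .init_conv(rng, kin, cout)
        pars[[sprintf("enc.L%d.B%d.in%d", l, b, k)]] <- .init_in(cout)
      }
      if (bc_in != cout)
        pars[[sprintf("enc.L%d.B%d.proj", l, b)]] <-
          list(W = matrix(rng_rnorm(rng, bc_in * cout, 0, .he_sd(bc_in)),
                          bc_in, cout), b = numeric(cout))
    }
    cin <- cout
  }
  w0 <- config$initial_width
  pars[["gc0"]] <- .init_gc(rng, 4L, w0)
  pars[["in0"]] <- .init_in(w0)
  gprev <- w0
  for (i in 1:3) {
    wi <- config$branch_width[i]
    bl <- config$branch_levels[[i]]
    pars[[sprintf("br%d.adapt", i)]] <- .init_gc(rng, gprev, wi)
    concat_w <- wi + sum(config$filters[bl]) + 1L
    for (r in 1:3) {
      for (k in 1:3) {
        fin <- if (r == 1L && k == 1L) concat_w else wi
        pars[[sprintf("br%d.RB%d.gc%d", i, r, k)]] <- .init_gc(rng, fin, wi)
        pars[[sprintf("br%d.RB%d.in%d", i, r, k)]] <- .init_in(wi)
      }
      if (r == 1L)
        pars[[sprintf("br%d.RB1.proj", i)]] <-
          list(W = matrix(rng_rnorm(rng, concat_w * wi, 0, .he_sd(concat_w)),
                          concat_w, wi), b = numeric(wi))
    }
    # bottleneck input is [h, vin*h, vin]: instance norm strips any
    # across-node constant (the broadcast inlet velocity included) from the
    # main path, so this unnormalized reinjection is the direct route for
    # the inlet-velocity response; the gated vin*h block makes the
    # multiplicative field-scales-with-velocity structure linearly
    # expressible
    pars[[sprintf("br%d.out", i)]] <- .init_gc(rng, 2L * wi + 1L, 7L,
                                               zero = TRUE)
    gprev <- wi
  }
  flat <- list()
  for (nm in names(pars)) for (pn in names(pars[[nm]]))
    flat[[paste(nm, pn, sep = ".")]] <- pars[[nm]][[pn]]
  topo <- loss_topology(template)
  structure(list(
    params = flat, config = config, stats = stats,
    template = list(nodes = template$nodes, tets = template$tets,
                    cap_faces = template$cap_faces,
                    fields_std = standardize_fields(template_fields, stats)),
    topo = topo,
    laplacian = scaled_laplacian(template),
    image_size = as.integer(image_size), spacing = spacing,
    seed = seed), class = "model_state")
}

# forward pass ------------------------------------------------------------

.fwd_ctx <- function(state, tape) {
  # wrap every parameter as a tape input once per forward pass
  nodes <- lapply(state$params, function(p) ad_input(tape, p))
  nodes
}

.encoder_block <- function(tape, x, pn, prefix, slope, dropout, rng) {
  h <- x
  for (k in 1:3) {
    cv <- pn[[paste0(prefix, ".conv", k, ".W")]]
    cb <- pn[[paste0(prefix, ".conv", k, ".b")]]
    h <- ad_conv3d(tape, h, cv, cb)
    h <- ad_instnorm(tape, h, pn[[paste0(prefix, ".in", k, ".gamma")]],
                     pn[[paste0(prefix, ".in", k, ".beta")]])
    h <- ad_leaky_relu(tape, h, slope)
  }
  h <- ad_spatial_dropout(tape, h, dropout, rng)
  skip <- x
  pw <- pn[[paste0(prefix, ".proj.W")]]
  if (!is.null(pw)) skip <- ad_conv1(tape, skip, pw, pn[[paste0(prefix, ".proj.b")]])
  ad_add(tape, h, skip)
}

.encode_image_nodes <- function(tape, img_node, pn, cfg, rng) {
  feats <- vector("list", cfg$levels)
  h <- img_node
  for (l in seq_len(cfg$levels)) {
    for (b in seq_len(cfg$blocks))
      h <- .encoder_block(tape, h, pn, sprintf("enc.L%d.B%d", l, b),
                          cfg$slope, cfg$dropout, rng)
    feats[[l]] <- h
    if (l < cfg$levels) h <- ad_maxpool3d(tape, h)
  }
  feats
}

.graph_conv <- function(tape, lap, x, w0, w1, b) {
  ad_bias(tape, ad_add(tape, ad_matmul(tape, x, w0),
                       ad_matmul(tape, ad_spmm(tape, lap, x), w1)), b)
}

.graph_block <- function(tape, lap, x, pn, prefix, slope, proj = NULL) {
  h <- x
  for (k in 1:3) {
    h <- .graph_conv(tape, lap, h,
                     pn[[paste0(prefix, ".gc", k, ".W0")]],
                     pn[[paste0(prefix, ".gc", k, ".W1")]],
                     pn[[paste0(prefix, ".gc", k, ".b")]])
    h <- ad_instnorm(tape, h, pn[[paste0(prefix, ".in", k, ".gamma")]],
                     pn[[paste0(prefix, ".in", k, ".beta")]])
    h <- ad_leaky_relu(tape, h, slope)
  }
  skip <- x
  if (!is.null(proj))
    skip <- ad_bias(tape, ad_matmul(tape, skip, pn[[paste0(prefix, ".proj.W")]]),
                    pn[[paste0(prefix, ".proj.b")]])
  ad_add(tape, h, skip)
}

# mm coordinates -> continuous 0-based index coordinates of encoder level l
.level_index_coords <- function(tape, coords, spacing, level) {
  f <- 2^(level - 1)
  # level-l voxel centers sit at spacing * (f*(i + 0.5) - 0.5) in mm
  ad_add(tape, ad_mul(tape, coords, 1 / (spacing * f)), 0.5 / f - 0.5)
}

#' Forward pass of the full model (tape form)
#'
#' Runs the encoder and the three transformation branches on an autodiff
#' tape. Used by training and gradient checks; [predict_mesh()] is the
#' user-facing wrapper.
#'
#' @param state a `model_state`.
#' @param image an `image_volume` matching the trained size.
#' @param inlet_velocity scalar, m/s.
#' @param tape an `ad_tape`; created if NULL.
#' @param training enable dropout.
#' @param rng `rng_stream` for dropout masks (training only).
#' @return list with `tape`, `branches` (each with ad nodes `coords`,
#'   `fields`), and `features` (encoder feature nodes).
#' @export
model_forward <- function(state, image, inlet_velocity, tape = NULL,
                          training = FALSE, rng = NULL) {
  cfg <- state$config
  d <- dim(image$voxels)
  if (d[1] != state$image_size)
    stop(sprintf("image size %d does not match the trained size %d",
                 d[1], state$image_size))
  if (is.null(tape)) tape <- ad_tape()
  tape$training <- training
  if (training && is.null(rng)) rng <- rng_stream(0L)
  pn <- .fwd_ctx(state, tape)
  img <- ad_const(tape, array(image$voxels, c(d, 1L)))
  feats <- .encode_image_nodes(tape, img, pn, cfg, rng)
  lap <- state$laplacian
  n <- nrow(state$template$nodes)
  dsz <- state$image_size * state$spacing

  coords <- ad_const(tape, state$template$nodes)
  fields <- ad_const(tape, state$template$fields_std)
  vin_col <- matrix(inlet_velocity, n, 1L)

  g <- .graph_conv(tape, lap,
                   ad_cbind(tape, ad_mul(tape, coords, 1 / dsz), vin_col),
                   pn[["gc0.W0"]], pn[["gc0.W1"]], pn[["gc0.b"]])
  g <- ad_leaky_relu(tape,
                     ad_instnorm(tape, g, pn[["in0.gamma"]], pn[["in0.beta"]]),
                     cfg$slope)

  branches <- vector("list", 3L)
  for (i in 1:3) {
    g <- .graph_conv(tape, lap, g,
                     pn[[sprintf("br%d.adapt.W0", i)]],
                     pn[[sprintf("br%d.adapt.W1", i)]],
                     pn[[sprintf("br%d.adapt.b", i)]])
    samp <- lapply(cfg$branch_levels[[i]], function(l)
      ad_trilinear(tape, feats[[l]],
                   .level_index_coords(tape, coords, state$spacing, l)))
    h <- do.call(ad_cbind, c(list(tape, g), samp, list(vin_col)))
    h <- .graph_block(tape, lap, h, pn, sprintf("br%d.RB1", i), cfg$slope,
                      proj = TRUE)
    h <- .graph_block(tape, lap, h, pn, sprintf("br%d.RB2", i), cfg$slope)
    h <- .graph_block(tape, lap, h, pn, sprintf("br%d.RB3", i), cfg$slope)
    gated <- ad_mul(tape, h, inlet_velocity)
    delta <- .graph_conv(tape, lap, ad_cbind(tape, h, gated, vin_col),
                         pn[[sprintf("br%d.out.W0", i)]],
                         pn[[sprintf("br%d.out.W1", i)]],
                         pn[[sprintf("br%d.out.b", i)]])
    if (any(!is.finite(delta$value)))
      stop(sprintf("non-finite delta in transformation branch %d", i))
    coords <- ad_add(tape, coords, ad_slice_cols(tape, delta, 1:3))
    fields <- ad_add(tape, fields, ad_slice_cols(tape, delta, 4:7))
    branches[[i]] <- list(coords = coords, fields = fields)
    g <- h
  }
  list(tape = tape, branches = branches, features = feats, params = pn)
}

#' Predict a mesh with pressure/velocity fields from an image
#'
#' Inference wrapper: deterministic (dropout off), returns the final branch
#' as a validated `volume_mesh` plus a de-standardized `field_set`, and the
#' wall time.
#'
#' @param state a trained `model_state`.
#' @param image an `image_volume`.
#' @param inlet_velocity scalar, m/s.
#' @return list with `mesh`, `fields`, `branches` (all three raw outputs),
#'   `seconds`.
#' @export
predict_mesh <- function(state, image, inlet_velocity) {
  t0 <- proc.time()[["elapsed"]]
  fw <- model_forward(state, image, inlet_velocity, training = FALSE)
  out <- fw$branches[[3]]
  mesh <- volume_mesh(out$coords$value, state$template$tets,
                      state$template$cap_faces, validate = FALSE)
  fields <- destandardize_fields(out$fields$value, state$stats)
  list(mesh = mesh, fields = fields,
       branches = lapply(fw$branches, function(b)
         list(coords = b$coords$value, fields = b$fields$value)),
       seconds = proc.time()[["elapsed"]] - t0)
}
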