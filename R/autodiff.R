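# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# A tape records operation nodes in creation order; ad_backward() seeds the
# output gradient and sweeps the tape in reverse, calling each node's
# vector-Jacobian product. Heavy kernels (conv3d, maxpool, trilinear) live in
# C++; everything else is plain vectorized R. This is deliberately small:
# strict shapes (no general broadcasting), double precision, single output.

#' Reverse-mode autodiff tape
#'
#' `ad_tape()` creates a recording tape; [ad_input()] registers a
#' differentiable leaf, [ad_const()] a constant; [ad_backward()] runs the
#' reverse sweep from a scalar output, after which every reachable input
#' node carries its gradient in `$grad`; [ad_value()] unwraps a node's
#' value. The loss builders `tape_*` in this package compose these nodes.
#'
#' @return `ad_tape()`: a tape; `ad_input`/`ad_const`: an `ad_node`.
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t$training <- FALSE
  class(t) <- "ad_tape"
  t
}

.ad_node <- function(tape, value, parents = list(), vjp = NULL,
                     requires = any(vapply(parents, function(p) p$requires, FALSE))) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjp <- vjp
  nd$requires <- requires
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "ad_node"
  nd
}

#' @rdname ad_tape
#' @param tape an `ad_tape`.
#' @param value a numeric array/matrix/vector.
#' @export
ad_input <- function(tape, value) .ad_node(tape, value, requires = TRUE)

#' @rdname ad_tape
#' @export
ad_const <- function(tape, value) .ad_node(tape, value, requires = FALSE)

.ad_wrap <- function(tape, x) if (inherits(x, "ad_node")) x else ad_const(tape, x)

#' @rdname ad_tape
#' @param x an `ad_node` or plain value.
#' @export
ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# run the reverse sweep from scalar output `out`; afterwards every input node
# reachable from `out` has its $grad filled in.
#' @rdname ad_tape
#' @param out the scalar output node to differentiate.
#' @param seed gradient seeded at the output (default 1).
#' @export
ad_backward <- function(tape, out, seed = 1) {
  stopifnot(length(out$value) == 1L)
  for (nd in tape$nodes) nd$grad <- NULL
  out$grad <- if (is.null(dim(out$value))) seed else array(seed, dim(out$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp) || !nd$requires) next
    gs <- nd$vjp(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(out)
}

# --- elementwise arithmetic (strict shapes; scalars allowed) ----------------

.same_or_scalar <- function(g, template) {
  # reduce a gradient to scalar if the forward operand was scalar
  if (length(template) == 1L) sum(g) else g
}

ad_add <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  .ad_node(tape, a$value + b$value, list(a, b), function(g)
    list(.same_or_scalar(g, a$value), .same_or_scalar(g, b$value)))
}

ad_sub <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  .ad_node(tape, a$value - b$value, list(a, b), function(g)
    list(.same_or_scalar(g, a$value), .same_or_scalar(-g, b$value)))
}

ad_mul <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$value; bv <- b$value
  .ad_node(tape, av * bv, list(a, b), function(g)
    list(.same_or_scalar(g * bv, av), .same_or_scalar(g * av, bv)))
}

ad_div <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$value; bv <- b$value
  .ad_node(tape, av / bv, list(a, b), function(g)
    list(.same_or_scalar(g / bv, av), .same_or_scalar(-g * av / bv^2, bv)))
}

ad_square <- function(tape, a) {
  av <- a$value
  .ad_node(tape, av^2, list(a), function(g) list(2 * g * av))
}

ad_sqrt <- function(tape, a) {
  v <- sqrt(a$value)
  .ad_node(tape, v, list(a), function(g) list(g / (2 * v)))
}

ad_abs <- function(tape, a) {
  av <- a$value
  .ad_node(tape, abs(av), list(a), function(g) list(g * sign(av)))
}

ad_sum <- function(tape, a) {
  av <- a$value
  .ad_node(tape, sum(av), list(a), function(g) {
    gv <- array(as.numeric(g), dim = if (is.null(dim(av))) length(av) else dim(av))
    if (is.null(dim(av))) as.numeric(gv) else gv
  })
}

ad_mean <- function(tape, a) {
  av <- a$value
  n <- length(av)
  .ad_node(tape, sum(av) / n, list(a), function(g) {
    gv <- array(as.numeric(g) / n, dim = if (is.null(dim(av))) length(av) else dim(av))
    if (is.null(dim(av))) as.numeric(gv) else gv
  })
}

# population standard deviation of a vector node
ad_pop_sd <- function(tape, a) {
  av <- as.numeric(a$value)
  n <- length(av)
  mu <- mean(av)
  v <- sqrt(sum((av - mu)^2) / n)
  .ad_node(tape, v, list(a), function(g) {
    if (v == 0) return(list(rep(0, n)))
    list(as.numeric(g) * (av - mu) / (n * v))
  })
}

ad_rowsums <- function(tape, a) {
  av <- a$value
  .ad_node(tape, rowSums(av), list(a), function(g)
    list(matrix(g, nrow(av), ncol(av))))
}

ad_rowmax <- function(tape, a) {
  av <- a$value
  idx <- max.col(av, ties.method = "first")
  v <- av[cbind(seq_len(nrow(av)), idx)]
  .ad_node(tape, v, list(a), function(g) {
    gm <- matrix(0, nrow(av), ncol(av))
    gm[cbind(seq_len(nrow(av)), idx)] <- g
    list(gm)
  })
}

ad_rowmin <- function(tape, a) {
  av <- a$value
  idx <- max.col(-av, ties.method = "first")
  v <- av[cbind(seq_len(nrow(av)), idx)]
  .ad_node(tape, v, list(a), function(g) {
    gm <- matrix(0, nrow(av), ncol(av))
    gm[cbind(seq_len(nrow(av)), idx)] <- g
    list(gm)
  })
}

# --- linear algebra ---------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$value; bv <- b$value
  .ad_node(tape, av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), crossprod(av, g)))
}

# constant sparse operator times dense node (graph convolution support term)
ad_spmm <- function(tape, S, x) {
  St <- Matrix::t(S)
  .ad_node(tape, as.matrix(S %*% x$value), list(x), function(g)
    list(as.matrix(St %*% g)))
}

# add a 1 x C bias row to every row of an N x C matrix
ad_bias <- function(tape, x, b) {
  b <- .ad_wrap(tape, b)
  xv <- x$value
  .ad_node(tape, sweep(xv, 2L, as.numeric(b$value), "+"), list(x, b),
           function(g) list(g, colSums(g)))
}

ad_index_rows <- function(tape, x, idx) {
  xv <- x$value
  .ad_node(tape, xv[idx, , drop = FALSE], list(x), function(g) {
    gm <- matrix(0, nrow(xv), ncol(xv))
    for (k in seq_along(idx)) gm[idx[k], ] <- gm[idx[k], ] + g[k, ]
    list(gm)
  })
}

ad_cbind <- function(tape, ...) {
  xs <- lapply(list(...), .ad_wrap, tape = tape)
  vals <- lapply(xs, function(x) {
    v <- x$value
    if (is.null(dim(v))) matrix(v, ncol = 1L) else v
  })
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ad_node(tape, do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(k) {
      gk <- g[, starts[k]:ends[k], drop = FALSE]
      if (is.null(dim(xs[[k]]$value))) as.numeric(gk) else gk
    })
  })
}

ad_slice_cols <- function(tape, x, cols) {
  xv <- x$value
  .ad_node(tape, xv[, cols, drop = FALSE], list(x), function(g) {
    gm <- matrix(0, nrow(xv), ncol(xv))
    gm[, cols] <- g
    list(gm)
  })
}

# row-wise cross product of two N x 3 matrices
ad_cross <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  v <- cbind(av[, 2] * bv[, 3] - av[, 3] * bv[, 2],
             av[, 3] * bv[, 1] - av[, 1] * bv[, 3],
             av[, 1] * bv[, 2] - av[, 2] * bv[, 1])
  .ad_node(tape, v, list(a, b), function(g) {
    # d/da (a x b)^T g = b x g ; d/db = g x a
    ga <- cbind(bv[, 2] * g[, 3] - bv[, 3] * g[, 2],
                bv[, 3] * g[, 1] - bv[, 1] * g[, 3],
                bv[, 1] * g[, 2] - bv[, 2] * g[, 1])
    gb <- cbind(g[, 2] * av[, 3] - g[, 3] * av[, 2],
                g[, 3] * av[, 1] - g[, 1] * av[, 3],
                g[, 1] * av[, 2] - g[, 2] * av[, 1])
    list(ga, gb)
  })
}

# normalize rows to unit length; vjp applies (I - n n^T)/|x| per row
ad_normalize_rows <- function(tape, x) {
  xv <- x$value
  len <- sqrt(rowSums(xv^2))
  if (any(len < 1e-12)) stop("zero-length row in normalize")
  nv <- xv / len
  .ad_node(tape, nv, list(x), function(g) {
    dot <- rowSums(g * nv)
    list((g - nv * dot) / len)
  })
}

# --- neural-net ops ---------------------------------------------------------

ad_leaky_relu <- function(tape, x, slope = 0.2) {
  xv <- x$value
  neg <- xv < 0
  v <- xv
  v[neg] <- slope * xv[neg]
  .ad_node(tape, v, list(x), function(g) {
    gv <- g
    gv[neg] <- slope * g[neg]
    list(gv)
  })
}

# instance normalization over the leading (spatial/node) dimensions, per
# channel (last dimension), with learnable per-channel gain/offset.
ad_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  gamma <- .ad_wrap(tape, gamma); beta <- .ad_wrap(tape, beta)
  xv <- x$value
  d <- dim(xv)
  C <- d[length(d)]
  n <- as.integer(prod(d) / C)
  xm <- xv
  dim(xm) <- c(n, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = n)
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  out <- xhat * rep(gv, each = n) + rep(bv, each = n)
  dim(out) <- d
  .ad_node(tape, out, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- gm * rep(gv, each = n)
    # dx = istd * (gh - mean(gh) - xhat * mean(gh * xhat)) per channel
    m1 <- colMeans(gh)
    m2 <- colMeans(gh * xhat)
    dx <- (gh - rep(m1, each = n) - xhat * rep(m2, each = n)) *
      rep(istd, each = n)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

ad_conv3d <- function(tape, x, w, b) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); dw <- dim(wv)
  dims <- as.integer(c(d[1:3], dw[4], dw[5]))
  out <- .cpp_conv3d_forward(xv, wv, as.numeric(b$value), dims)
  .ad_node(tape, out, list(x, w, b), function(g) {
    gr <- .cpp_conv3d_backward(xv, wv, g, dims)
    list(gr$dx, gr$dw, gr$db)
  })
}

# 1x1x1 channel-mixing convolution (residual projections)
ad_conv1 <- function(tape, x, w, b) {
  xv <- x$value; wv <- w$value
  d <- dim(xv)
  dims <- as.integer(c(d[1:3], dim(wv)[1], dim(wv)[2]))
  out <- .cpp_conv1_forward(xv, wv, as.numeric(b$value), dims)
  nvox <- prod(d[1:3])
  .ad_node(tape, out, list(x, w, b), function(g) {
    gm <- matrix(g, nvox, dims[5])
    xm <- matrix(xv, nvox, dims[4])
    dx <- gm %*% t(wv)
    dim(dx) <- d
    list(dx, crossprod(xm, gm), colSums(gm))
  })
}

ad_maxpool3d <- function(tape, x) {
  xv <- x$value
  d <- dim(xv)
  r <- .cpp_maxpool3d_forward(xv, as.integer(d))
  .ad_node(tape, r$out, list(x), function(g)
    list(.cpp_maxpool3d_backward(g, r$argmax, as.integer(d))))
}

# trilinear sampling: grid is a constant or node, points differentiable
ad_trilinear <- function(tape, grid, points) {
  grid <- .ad_wrap(tape, grid); points <- .ad_wrap(tape, points)
  gv <- grid$value; pv <- points$value
  d <- dim(gv)
  if (length(d) == 3L) d <- c(d, 1L)
  out <- .cpp_trilinear_forward(gv, pv, as.integer(d))
  .ad_node(tape, out, list(grid, points), function(g) {
    r <- .cpp_trilinear_backward(gv, pv, g, as.integer(d))
    list(r$dgrid, r$dpts)
  })
}

# channel dropout (whole channels zeroed), active only in training mode
ad_spatial_dropout <- function(tape, x, rate, rng) {
  if (!tape$training || rate <= 0) return(x)
  xv <- x$value
  d <- dim(xv)
  C <- d[length(d)]
  keep <- rng_runif(rng, C) >= rate
  scale <- ifelse(keep, 1 / (1 - rate), 0)
  xm <- matrix(xv, prod(d) / C, C)
  out <- sweep(xm, 2L, scale, "*")
  dim(out) <- d
  .ad_node(tape, out, list(x), function(g) {
    gm <- matrix(g, prod(d) / C, C)
    gm <- sweep(gm, 2L, scale, "*")
    dim(gm) <- d
    list(gm)
  })
}
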