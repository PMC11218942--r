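# Pseudo-MRI rasterization: bright tubular lumen on a darker, noisy tissue
# background with smooth confounders (blobs, multiplicative bias field).
# Emulates the contrast structure of a whole-heart bSSFP crop, not its physics.

#' Rasterize a mesh into a pseudo-MRI volume and binary mask
#'
#' `image = background + (lumen - background) * mask`, plus `n_blobs` smooth
#' Gaussian "tissue" blobs, a low-frequency multiplicative bias field, and
#' i.i.d. Gaussian noise; intensities clipped to [0, 1]. Bit-reproducible
#' under `seed`.
#'
#' @param mesh a `volume_mesh` in mm, lying inside the grid.
#' @param grid_size voxels per edge (cubic).
#' @param spacing mm per voxel.
#' @param seed integer seed for blobs/bias/noise.
#' @param lumen,background mean intensities of vessel and tissue.
#' @param noise_sd Gaussian noise standard deviation (0 disables).
#' @param n_blobs number of smooth tissue blobs (0 disables).
#' @param bias_amp amplitude of the multiplicative bias field (0 disables).
#' @return list with `image` (`image_volume`) and `mask` (integer array).
#' @export
rasterize_pseudo_mri <- function(mesh, grid_size, spacing = 1.0, seed = 1L,
                                 lumen = 0.8, background = 0.3,
                                 noise_sd = 0.05, n_blobs = 3L,
                                 bias_amp = 0.15) {
  d <- as.integer(grid_size)
  grid <- image_volume(array(0, rep(d, 3L)), spacing = spacing)
  lo <- apply(mesh$nodes, 2L, min); hi <- apply(mesh$nodes, 2L, max)
  if (any(lo < 0) || any(hi > (d - 1) * spacing))
    stop("mesh extends outside the image grid")
  mask <- voxelize(mesh, grid)
  img <- background + (lumen - background) * mask
  rng <- rng_stream(seed)
  ax <- seq_len(d) - 1
  if (n_blobs > 0L) {
    for (b in seq_len(n_blobs)) {
      cen <- rng_runif(rng, 3, 0, d - 1)
      sig <- rng_runif(rng, 1, d / 16, d / 8)
      amp <- rng_runif(rng, 1, 0.08, 0.22)
      gx <- exp(-(ax - cen[1])^2 / (2 * sig^2))
      gy <- exp(-(ax - cen[2])^2 / (2 * sig^2))
      gz <- exp(-(ax - cen[3])^2 / (2 * sig^2))
      img <- img + amp * outer(outer(gx, gy), gz)
    }
  }
  if (bias_amp > 0) {
    ph <- rng_runif(rng, 3, 0, 2 * pi)
    fx <- 1 + bias_amp * sin(2 * pi * ax / d + ph[1])
    fy <- 1 + bias_amp * sin(2 * pi * ax / d + ph[2])
    fz <- 1 + bias_amp * sin(2 * pi * ax / d + ph[3])
    img <- img * outer(outer(fx, fy), fz)^(1 / 3)
  }
  if (noise_sd > 0)
    img <- img + array(rng_rnorm(rng, d^3, 0, noise_sd), rep(d, 3L))
  img <- pmin(1, pmax(0, img))
  list(image = image_volume(array(img, rep(d, 3L)), spacing = spacing),
       mask = mask)
}
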