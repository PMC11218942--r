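# Field transforms between physical space (Pa, m/s) and training space.
# Pressure is signed-cube-rooted first (gauge pressures can be negative) to
# tame its skewed distribution, then all four channels are standardized with
# global statistics over the training split.

#' Signed cube root
#'
#' `sign(x) * |x|^(1/3)`: odd, monotone, defined for negative gauge pressures.
#' @param x numeric.
#' @return transformed values.
#' @export
signed_cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

#' Fit standardization statistics over training field sets
#'
#' Per-channel mean and population standard deviation, computed in the space
#' the losses see: cube-rooted pressure and raw velocity components, pooled
#' over all nodes of all supplied cases.
#'
#' @param field_sets list of `field_set` objects.
#' @return object of class `field_stats` with `mean` and `sd` (length 4:
#'   `p_cbrt`, `vx`, `vy`, `vz`).
#' @export
fit_stats <- function(field_sets) {
  if (!length(field_sets)) stop("no field sets supplied")
  mats <- lapply(field_sets, function(f)
    cbind(signed_cube_root(f$pressure), f$velocity))
  x <- do.call(rbind, mats)
  if (nrow(x) < 2L) stop("need at least 2 nodes to fit statistics")
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
  if (any(sd <= 0))
    stop("constant channel (zero standard deviation): ",
         paste(c("p_cbrt", "vx", "vy", "vz")[sd <= 0], collapse = ", "))
  structure(list(mean = stats::setNames(mu, c("p_cbrt", "vx", "vy", "vz")),
                 sd = stats::setNames(sd, c("p_cbrt", "vx", "vy", "vz"))),
            class = "field_stats")
}

#' Standardize fields into training space
#'
#' @param fields a `field_set` (physical units).
#' @param stats a `field_stats` from [fit_stats()].
#' @return N x 4 matrix (standardized cube-root pressure, vx, vy, vz).
#' @export
standardize_fields <- function(fields, stats) {
  if (!inherits(stats, "field_stats")) stop("stats must come from fit_stats()")
  x <- cbind(signed_cube_root(fields$pressure), fields$velocity)
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' De-standardize fields back to physical units
#'
#' Inverts [standardize_fields()]; the pressure channel is cubed back to Pa.
#'
#' @param mat N x 4 standardized matrix.
#' @param stats a `field_stats`.
#' @return a `field_set` in Pa / m/s.
#' @export
destandardize_fields <- function(mat, stats) {
  if (!inherits(stats, "field_stats")) stop("stats must come from fit_stats()")
  x <- sweep(sweep(as.matrix(mat), 2L, stats$sd, "*"), 2L, stats$mean, "+")
  field_set(pressure = x[, 1]^3, velocity = x[, 2:4, drop = FALSE])
}
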