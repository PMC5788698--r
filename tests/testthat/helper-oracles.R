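# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all group-label
# arrangements (no ties assumed).
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Volume of {sdf <= 0} by dense-grid integration with linear partial-voxel
# weighting; independent of the meshing pipeline.
numeric_volume <- function(sdf, lower, upper, step) {
  xs <- seq(lower[1] + step / 2, upper[1], by = step)
  ys <- seq(lower[2] + step / 2, upper[2], by = step)
  zs <- seq(lower[3] + step / 2, upper[3], by = step)
  g <- expand.grid(x = xs, y = ys, z = zs)
  d <- sdf(g$x, g$y, g$z)
  w <- pmin(pmax(0.5 - d / step, 0), 1)
  sum(w) * step^3
}

# Surface area as the derivative of the dilated volume (Steiner):
# A = dV(r)/dr approximated by central difference of numeric volumes.
numeric_area <- function(sdf, lower, upper, step, eps = NULL) {
  eps <- eps %||% step
  vplus <- numeric_volume(function(x, y, z) sdf(x, y, z) - eps,
                          lower - 2 * eps, upper + 2 * eps, step)
  vminus <- numeric_volume(function(x, y, z) sdf(x, y, z) + eps,
                           lower - 2 * eps, upper + 2 * eps, step)
  (vplus - vminus) / (2 * eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a minimal single-voxel labeled volume for block-mesh oracles
single_voxel_volume <- function(edge_nm = 10) {
  lab <- array(0L, dim = c(3, 3, 3))
  lab[2, 2, 2] <- 4L # matrix label: volumetric compartment
  labeled_volume(lab, voxel_size = edge_nm)
}
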