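# Independent oracles and small fixture builders shared across tests.

# Brute-force OLS: minimise the residual sum of squares over an iteratively
# refined (slope, intercept) grid. Independent of the closed-form path.
oracle_ols_grid <- function(x, y, rounds = 10, pts = 41) {
  s_half <- 10 * (max(abs(y)) + 1) / (stats::sd(x) + 1)
  i_half <- 10 * (max(abs(y)) + 1)
  s_mid <- 0
  i_mid <- mean(y)
  for (r in seq_len(rounds)) {
    s_grid <- seq(s_mid - s_half, s_mid + s_half, length.out = pts)
    i_grid <- seq(i_mid - i_half, i_mid + i_half, length.out = pts)
    ssr <- outer(s_grid, i_grid, Vectorize(function(s, i) {
      sum((y - i - s * x)^2)
    }))
    best <- arrayInd(which.min(ssr), dim(ssr))
    s_mid <- s_grid[best[1]]
    i_mid <- i_grid[best[2]]
    s_half <- 3 * diff(s_grid[1:2])
    i_half <- 3 * diff(i_grid[1:2])
  }
  list(slope = s_mid, intercept = i_mid)
}

# A small noiseless solid phantom that fits a 64^3 grid at 0.25 mm.
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = 64, implant_diameter_mm = 8, cv_diameter_mm = 5,
         pore_fraction = 0, spike_count = 0, noise_sd_hu = 0),
    list(...))
  do.call(phantom_spec, args)
}

# Random rigid motion (proper rotation + translation) under the current RNG.
random_rigid_motion <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_m <- qr(m)
  rot <- qr.Q(qr_m) %*% diag(sign(diag(qr.R(qr_m))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = stats::rnorm(3, 0, 20))
}

apply_motion <- function(motion, p) as.numeric(motion$rot %*% p + motion$shift)

# A tiny deterministic voxel volume with distinct values.
tiny_volume <- function(dims = c(4, 3, 2), spacing = 1, origin = c(0, 0, 0)) {
  voxel_volume(array(seq_len(prod(dims)), dims), spacing_mm = spacing,
               origin_mm = origin)
}
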