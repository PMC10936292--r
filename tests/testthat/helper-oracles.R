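# Shared fixtures and independent scalar oracles.  The oracles re-derive the
# model arithmetic in plain scalar code, deliberately separate from the
# package's vectorized implementation.

rs_test <- function() raster_spec(96, 96, fov_deg = 96 * sqrt(2) / 8)  # 8 px/deg
gs_test <- function() grid_spec(extent_deg = 10)

field1 <- function(rho = 0.3, s = 0.2, lambda = 0.5, sigma = 2,
                   center = c(0, 0), alpha = 3) {
  distortion_field(list(make_kernel(center, sigma, lambda, rho, s, alpha)))
}

# Independent scalar evaluation of one kernel's backward-sampling offset at
# a single point (degrees).
oracle_offset <- function(center, sigma, rho, s, alpha, p) {
  vx <- p[1] - center[1]
  vy <- p[2] - center[2]
  r <- sqrt(vx^2 + vy^2)
  r0 <- (alpha - 0.5) * sigma
  r1 <- alpha * sigma
  Tt <- if (r <= r0) 1 else if (r >= r1) 0 else {
    t <- (r - r0) / (r1 - r0)
    1 - (3 * t^2 - 2 * t^3)
  }
  g <- exp(-r^2 / (2 * sigma^2)) * Tt
  th <- rho * (r / sigma) * exp(0.5 - r^2 / (2 * sigma^2)) * Tt
  bx <- (cos(th) * vx - sin(th) * vy) * (1 + s * g)
  by <- (sin(th) * vx + cos(th) * vy) * (1 + s * g)
  c(center[1] + bx, center[2] + by) - p
}

# Independent per-pixel rasterization of the Amsler line layout.
oracle_amsler_mask <- function(gs, rs) {
  s <- rs$px_per_deg
  E <- gs$extent_deg / 2
  lw <- gs$line_width_px
  tol <- 1e-9
  m <- matrix(FALSE, rs$height_px, rs$width_px)
  n <- floor(E / gs$pitch_deg + tol)
  for (j in seq_len(rs$height_px)) {
    for (i in seq_len(rs$width_px)) {
      xr <- ((i - 0.5) - rs$width_px / 2) / s
      yr <- (rs$height_px / 2 - (j - 0.5)) / s
      on <- FALSE
      for (kk in -n:n) {
        o <- kk * gs$pitch_deg
        if (abs(xr - o) * s <= lw / 2 + tol && abs(yr) <= E + tol) on <- TRUE
        if (abs(yr - o) * s <= lw / 2 + tol && abs(xr) <= E + tol) on <- TRUE
      }
      if (gs$diagonals && abs(xr) <= E + tol && abs(yr) <= E + tol) {
        if (abs(xr - yr) / sqrt(2) * s <= lw / 2 + tol) on <- TRUE
        if (abs(xr + yr) / sqrt(2) * s <= lw / 2 + tol) on <- TRUE
      }
      if (gs$fixation_marker && sqrt(xr^2 + yr^2) * s <= 2 * lw + tol) on <- TRUE
      m[j, i] <- on
    }
  }
  m
}

# Brute-force Pearson chi-square: sum (O - E)^2 / E after dropping empty
# rows/columns.
chisq_brute <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Per-pixel kernel-weight sum of a field (for support scans).
field_weight_matrix <- function(field, rs) {
  ctr <- metamorphsim:::pixel_centers_deg(rs)
  W <- matrix(0, rs$height_px, rs$width_px)
  pts <- cbind(rep(ctr$x, each = rs$height_px), rep(ctr$y, times = rs$width_px))
  for (k in field$kernels) W <- W + matrix(kernel_weight(k, pts), rs$height_px)
  W
}
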