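# Evaluate one kernel's backward-sampling offset (degrees) at points.
# v = p - center, r = |v|.  The backward sample point composes a tangential
# rotation with a radial scale:
#   theta(r) = rho * (r / sigma) * exp(1/2 - r^2 / (2 sigma^2)) * T(r)
#   g(r)     = exp(-r^2 / (2 sigma^2)) * T(r)
#   sample   = center + Rot(theta) %*% v * (1 + s * g(r))
# where T is the smooth truncation window, so contributions are exactly
# zero on and outside the support boundary.
kernel_offset <- function(kernel, px, py) {
  vx <- px - kernel$center[1]
  vy <- py - kernel$center[2]
  r2 <- vx * vx + vy * vy
  r <- sqrt(r2)
  sig <- kernel$sigma_deg
  tw <- trunc_window(r, sig, kernel$boundary_alpha)
  dx <- numeric(length(px))
  dy <- numeric(length(py))
  idx <- which(tw > 0)
  if (length(idx)) {
    ri <- r[idx]
    e2 <- exp(-r2[idx] / (2 * sig^2))
    th <- kernel$rotation_strength_rad * (ri / sig) * exp(0.5) * e2 * tw[idx]
    sc <- 1 + kernel$radial_stretch * e2 * tw[idx]
    ct <- cos(th); st <- sin(th)
    bx <- (ct * vx[idx] - st * vy[idx]) * sc
    by <- (st * vx[idx] + ct * vy[idx]) * sc
    dx[idx] <- bx - vx[idx]
    dy[idx] <- by - vy[idx]
  }
  list(dx = dx, dy = dy)
}

#' Displacement of the visual field at arbitrary points
#'
#' Sums, over all kernels of a field, the backward-sampling offset produced
#' by composing each kernel's tangential rotation with its radial
#' stretch/squeeze (rotation applied first).  The result is the offset, in
#' degrees, from a percept location to the scene location it samples; it is
#' identically zero outside the union of kernel supports and everywhere when
#' all rotation and stretch amplitudes are zero.
#'
#' @param field A [distortion_field()].
#' @param points_deg A 2-vector or n x 2 matrix of visual-field points
#'   (degrees).
#' @return An n x 2 matrix of displacements (degrees).
#' @export
displacement_at <- function(field, points_deg) {
  stopifnot(inherits(field, "distortion_field"))
  p <- as_points(points_deg)
  if (any(!is.finite(p))) stopf("points must be finite")
  d <- matrix(0, nrow(p), 2L)
  for (k in field$kernels) {
    o <- kernel_offset(k, p[, 1], p[, 2])
    d[, 1] <- d[, 1] + o$dx
    d[, 2] <- d[, 2] + o$dy
  }
  d
}

# Multiplicative luminance gain prod_k (1 - lambda_k * w_k) at points.
luminance_gain_at <- function(field, points_deg) {
  p <- as_points(points_deg)
  g <- rep(1, nrow(p))
  for (k in field$kernels)
    if (k$luminance_loss > 0) g <- g * (1 - k$luminance_loss * kernel_weight(k, p))
  g
}

#' Rasterize a distortion field to displacement and luminance maps
#'
#' Evaluates [displacement_at()] (converted to pixel units) and the
#' multiplicative luminance gain `prod_k (1 - lambda_k * w_k)` at every
#' pixel center of the raster.  Per-kernel work is restricted to the
#' kernel's bounding box, so fields stay cheap on large rasters.
#'
#' @param field A [distortion_field()].
#' @param rs A [raster_spec()].
#' @return An object of class `distortion_maps`: list with `displacement`
#'   (height x width x 2 array, pixel units; slice 1 = x/column offset,
#'   slice 2 = y/row offset, row-down positive), `luminance`
#'   (height x width gain matrix in \[0, 1\]) and `raster_spec`.
#' @export
render_maps <- function(field, rs) {
  stopifnot(inherits(field, "distortion_field"), inherits(rs, "raster_spec"))
  h <- rs$height_px; w <- rs$width_px
  ctr <- pixel_centers_deg(rs)
  dx <- matrix(0, h, w); dy <- matrix(0, h, w); gain <- matrix(1, h, w)
  for (k in field$kernels) {
    rad <- k$boundary_alpha * k$sigma_deg
    ci <- which(abs(ctr$x - k$center[1]) <= rad)
    ri <- which(abs(ctr$y - k$center[2]) <= rad)
    if (!length(ci) || !length(ri)) next
    nr <- length(ri); nc <- length(ci)
    px <- matrix(ctr$x[ci], nr, nc, byrow = TRUE)
    py <- matrix(ctr$y[ri], nr, nc)
    o <- kernel_offset(k, px, py)
    dx[ri, ci] <- dx[ri, ci] + o$dx
    dy[ri, ci] <- dy[ri, ci] + o$dy
    if (k$luminance_loss > 0) {
      r <- sqrt((px - k$center[1])^2 + (py - k$center[2])^2)
      wt <- exp(-r^2 / (2 * k$sigma_deg^2)) * trunc_window(r, k$sigma_deg, k$boundary_alpha)
      gain[ri, ci] <- gain[ri, ci] * (1 - k$luminance_loss * wt)
    }
  }
  s <- rs$px_per_deg
  disp <- array(0, c(h, w, 2L))
  disp[, , 1L] <- dx * s          # +x degrees -> +columns
  disp[, , 2L] <- -dy * s         # +y degrees (up) -> -rows (rows grow down)
  structure(list(displacement = disp, luminance = gain, raster_spec = rs),
            class = "distortion_maps")
}

#' @export
print.distortion_maps <- function(x, ...) {
  mag <- sqrt(x$displacement[, , 1]^2 + x$displacement[, , 2]^2)
  cat(sprintf("<distortion_maps> %d x %d px; |displacement| max %.3g px; luminance gain min %.3g\n",
              dim(x$luminance)[1], dim(x$luminance)[2], max(mag), min(x$luminance)))
  invisible(x)
}

# Bilinear sampling of a matrix at continuous (row, col) index positions
# (pixel j's center is at index j), clamping out-of-bounds samples to the
# edge.  Exact at integer positions.
bilinear_sample <- function(m, rr, cc) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(rr); fr <- rr - r0
  c0 <- floor(cc); fc <- cc - c0
  r0a <- clamp(r0, 1, h); r1a <- clamp(r0 + 1, 1, h)
  c0a <- clamp(c0, 1, w); c1a <- clamp(c0 + 1, 1, w)
  i00 <- (c0a - 1) * h + r0a
  i01 <- (c1a - 1) * h + r0a
  i10 <- (c0a - 1) * h + r1a
  i11 <- (c1a - 1) * h + r1a
  (1 - fr) * ((1 - fc) * m[i00] + fc * m[i01]) +
    fr * ((1 - fc) * m[i10] + fc * m[i11])
}

#' Warp an image through displacement and luminance maps
#'
#' Backward mapping: output pixel `p` samples the input image at
#' `p + displacement(p)` with bilinear interpolation (out-of-bounds samples
#' clamp to the nearest edge pixel), then is multiplied by the luminance
#' gain at `p`.  With a zero displacement and unit gain the output is
#' bit-exact identical to the input.
#'
#' @param image Numeric matrix (gray) or height x width x 3 array (RGB),
#'   values in \[0, 1\].
#' @param displacement A `distortion_maps` object or a height x width x 2
#'   displacement array in pixel units.
#' @param luminance Optional height x width gain matrix; taken from
#'   `displacement` when that is a `distortion_maps` object.
#' @return Warped image, same shape as the input.
#' @export
warp_image <- function(image, displacement, luminance = NULL) {
  if (inherits(displacement, "distortion_maps")) {
    if (is.null(luminance)) luminance <- displacement$luminance
    displacement <- displacement$displacement
  }
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  if (!identical(dim(displacement)[1:2], c(h, w)))
    stopf("image (%d x %d) and displacement map (%d x %d) shapes differ",
          h, w, dim(displacement)[1], dim(displacement)[2])
  if (!is.null(luminance) && !identical(dim(luminance), c(h, w)))
    stopf("image and luminance map shapes differ")
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) + displacement[, , 1L]
  rr <- matrix(seq_len(h), h, w) + displacement[, , 2L]
  warp1 <- function(m) {
    out <- matrix(bilinear_sample(m, rr, cc), h, w)
    if (!is.null(luminance)) out <- out * luminance
    out
  }
  if (length(dims) == 2L) return(warp1(image))
  out <- image
  for (ch in seq_len(dims[3])) out[, , ch] <- warp1(image[, , ch])
  out
}

#' Invert a dense displacement map by fixed-point iteration
#'
#' Finds the map `dinv` with `d(p + dinv(p)) + dinv(p) = 0` by iterating
#' `dinv <- -d(p + dinv(p))` (displacements sampled bilinearly) until the
#' largest per-pixel update falls below `tol`.  The plain iteration only
#' contracts when the displacement gradient stays below 1; for steeper (but
#' still fold-free) fields the update is under-relaxed, retrying with
#' damping factors 1, 1/2 and 1/4 before giving up.  Composing the forward
#' warp after the converged inverse moves no pixel by more than roughly
#' `tol`.
#'
#' @param displacement A `distortion_maps` object or height x width x 2
#'   displacement array (pixel units).
#' @param tol Convergence tolerance in pixels (> 0).
#' @param max_iter Iteration cap per damping level; non-convergence raises
#'   an error reporting the worst composition residual.
#' @return A height x width x 2 inverse displacement array with attributes
#'   `iterations`, `damping` and `max_residual_px`.
#' @export
invert_displacement <- function(displacement, tol = 0.01, max_iter = 100) {
  if (inherits(displacement, "distortion_maps"))
    displacement <- displacement$displacement
  if (!is_number(tol) || tol <= 0) stopf("'tol' must be > 0")
  h <- dim(displacement)[1]; w <- dim(displacement)[2]
  dx <- displacement[, , 1L]; dy <- displacement[, , 2L]
  cc0 <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr0 <- matrix(seq_len(h), h, w)
  for (omega in c(1, 0.5, 0.25)) {
    ix <- matrix(0, h, w); iy <- matrix(0, h, w)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sx <- matrix(bilinear_sample(dx, rr0 + iy, cc0 + ix), h, w)
      sy <- matrix(bilinear_sample(dy, rr0 + iy, cc0 + ix), h, w)
      ux <- -sx - ix; uy <- -sy - iy
      ix <- ix + omega * ux; iy <- iy + omega * uy
      if (max(abs(ux), abs(uy)) < tol) {
        converged <- TRUE
        break
      }
    }
    if (converged) {
      out <- array(0, c(h, w, 2L))
      out[, , 1L] <- ix; out[, , 2L] <- iy
      attr(out, "iterations") <- it
      attr(out, "damping") <- omega
      attr(out, "max_residual_px") <-
        max(composition_residual_arrays(dx, dy, ix, iy))
      return(out)
    }
  }
  res <- composition_residual_arrays(dx, dy, ix, iy)
  stopf("displacement inversion did not converge in %d iterations (worst residual %.4g px)",
        max_iter, max(res))
}

composition_residual_arrays <- function(dx, dy, ix, iy) {
  h <- nrow(dx); w <- ncol(dx)
  cc0 <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr0 <- matrix(seq_len(h), h, w)
  rx <- matrix(bilinear_sample(dx, rr0 + iy, cc0 + ix), h, w) + ix
  ry <- matrix(bilinear_sample(dy, rr0 + iy, cc0 + ix), h, w) + iy
  sqrt(rx^2 + ry^2)
}

#' Residual of composing a forward displacement after a candidate inverse
#'
#' Per-pixel magnitude of `d(p + dinv(p)) + dinv(p)` in pixels; the zero
#' matrix iff `dinv` inverts `d` exactly on the raster.
#'
#' @param displacement Forward map (`distortion_maps` or h x w x 2 array).
#' @param inverse Candidate inverse displacement (h x w x 2 array).
#' @return Height x width matrix of residual magnitudes (pixels).
#' @export
composition_residual <- function(displacement, inverse) {
  if (inherits(displacement, "distortion_maps"))
    displacement <- displacement$displacement
  if (inherits(inverse, "distortion_maps")) inverse <- inverse$displacement
  composition_residual_arrays(displacement[, , 1L], displacement[, , 2L],
                              inverse[, , 1L], inverse[, , 2L])
}
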