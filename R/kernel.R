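#' Construct a metamorphopsia distortion kernel
#'
#' One circular unit of metamorphopsia, parameterized by localization
#' (`center`), size (`sigma_deg`, the Gaussian standard deviation),
#' luminance perception (`luminance_loss`) and shape (a tangential rotation
#' and a radial stretch/squeeze).  The kernel's influence follows a Gaussian
#' profile truncated smoothly to exactly zero at `boundary_alpha * sigma_deg`
#' from the center, so every kernel has compact support: the closed disk of
#' that radius.
#'
#' Perceptual-loss, rotational and spatial components live on one record but
#' act independently and share only the size parameters (`center`,
#' `sigma_deg`, `boundary_alpha`); zeroing any subset recovers the simpler
#' single-effect kernels.
#'
#' @param center Kernel center, visual-field degrees (2-vector).
#' @param sigma_deg Gaussian standard deviation, degrees (> 0).
#' @param luminance_loss Peak multiplicative luminance sensitivity loss in
#'   \[0, 1\]; 1 means total darkness at the kernel center.
#' @param rotation_strength_rad Signed peak tangential rotation (radians);
#'   positive rotates counter-clockwise in visual-field coordinates
#'   (x right, y up).
#' @param radial_stretch Signed radial scale amplitude (> -1); positive
#'   stretches outward, negative squeezes inward.
#' @param boundary_alpha Support truncation radius in multiples of
#'   `sigma_deg` (>= 1).
#' @return An object of class `distortion_kernel`.
#' @examples
#' k <- make_kernel(c(0, 0), sigma_deg = 2, luminance_loss = 0.5,
#'                  rotation_strength_rad = 0.3, radial_stretch = 0.2)
#' kernel_weight(k, c(2, 0))  # exp(-1/2)
#' @export
make_kernel <- function(center, sigma_deg, luminance_loss = 0,
                        rotation_strength_rad = 0, radial_stretch = 0,
                        boundary_alpha = 3) {
  center <- check_point2(center, "center")
  if (!is_number(sigma_deg) || sigma_deg <= 0)
    stopf("'sigma_deg' must be a positive real (got %s)", format(sigma_deg))
  if (!is_number(luminance_loss) || luminance_loss < 0 || luminance_loss > 1)
    stopf("'luminance_loss' must lie in [0, 1] (got %s)", format(luminance_loss))
  if (!is_number(rotation_strength_rad))
    stopf("'rotation_strength_rad' must be a finite real")
  if (!is_number(radial_stretch) || radial_stretch <= -1)
    stopf("'radial_stretch' must be a real > -1 (got %s)", format(radial_stretch))
  if (!is_number(boundary_alpha) || boundary_alpha < 1)
    stopf("'boundary_alpha' must be >= 1 (got %s)", format(boundary_alpha))
  structure(list(
    center = center,
    sigma_deg = as.numeric(sigma_deg),
    luminance_loss = as.numeric(luminance_loss),
    rotation_strength_rad = as.numeric(rotation_strength_rad),
    radial_stretch = as.numeric(radial_stretch),
    boundary_alpha = as.numeric(boundary_alpha)
  ), class = "distortion_kernel")
}

# Smooth truncation window: 1 inside (alpha - 0.5) * sigma, smoothstep down
# to exactly 0 at alpha * sigma and beyond.
trunc_window <- function(r, sigma, alpha) {
  t <- clamp((r - (alpha - 0.5) * sigma) / (0.5 * sigma), 0, 1)
  1 - t * t * (3 - 2 * t)
}

#' Gaussian kernel weight at points of the visual field
#'
#' The truncated Gaussian profile `exp(-r^2 / (2 sigma^2))` smoothly brought
#' to exactly 0 at `boundary_alpha * sigma` from the kernel center.
#'
#' @param kernel A [make_kernel()] object.
#' @param points_deg A 2-vector or n x 2 matrix of visual-field points
#'   (degrees).
#' @return Numeric vector of weights in \[0, 1\].
#' @export
kernel_weight <- function(kernel, points_deg) {
  stopifnot(inherits(kernel, "distortion_kernel"))
  p <- as_points(points_deg)
  r <- sqrt((p[, 1] - kernel$center[1])^2 + (p[, 2] - kernel$center[2])^2)
  exp(-r^2 / (2 * kernel$sigma_deg^2)) *
    trunc_window(r, kernel$sigma_deg, kernel$boundary_alpha)
}

#' Per-eye metamorphopsia field (mixture of distortion kernels)
#'
#' A mixture of [make_kernel()] units modeling a complex metamorphopsia in
#' one eye.  The empty field is the identity (no distortion).  Kernel order
#' never affects any rasterized output: displacements add and luminance
#' gains multiply across kernels.
#'
#' @param kernels List of `distortion_kernel` objects (possibly empty).
#' @param eye `"left"` or `"right"`.
#' @return An object of class `distortion_field`.
#' @export
distortion_field <- function(kernels = list(), eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (inherits(kernels, "distortion_kernel")) kernels <- list(kernels)
  if (!is.list(kernels) || !all(vapply(kernels, inherits, TRUE, "distortion_kernel")))
    stopf("'kernels' must be a list of distortion_kernel objects")
  structure(list(kernels = kernels, eye = eye), class = "distortion_field")
}

n_kernels <- function(field) length(field$kernels)

#' @export
print.distortion_kernel <- function(x, ...) {
  cat(sprintf(
    "<distortion_kernel> center (%.3g, %.3g) deg, sigma %.3g deg, lambda %.3g, rho %.3g rad, stretch %.3g, alpha %.3g\n",
    x$center[1], x$center[2], x$sigma_deg, x$luminance_loss,
    x$rotation_strength_rad, x$radial_stretch, x$boundary_alpha))
  invisible(x)
}

#' @export
print.distortion_field <- function(x, ...) {
  cat(sprintf("<distortion_field> %s eye, %d kernel%s\n", x$eye,
              n_kernels(x), if (n_kernels(x) == 1) "" else "s"))
  for (k in x$kernels) print(k)
  invisible(x)
}

#' @export
summary.distortion_field <- function(object, ...) {
  print(object)
  if (n_kernels(object) > 0) {
    e <- distortion_extent(object)
    cat(sprintf("extent: center (%.3g, %.3g) deg, radius %.3g deg\n",
                e$center[1], e$center[2], e$radius))
  }
  invisible(object)
}
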