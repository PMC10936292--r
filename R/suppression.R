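#' Build a gaze-locked dark suppression spot for a distortion field
#'
#' The spot is centered on the distortion extent centroid and sized as a
#' fraction (`scale`) of the extent radius, so the protocol levels 0, 25,
#' 90 and 120 percent are `scale` = 0, 0.25, 0.90 and 1.20.  Because the
#' extent radius covers every kernel's support disk, any `scale >= 1` spot
#' covers all distorted points.
#'
#' The default `"radius"` sizing interprets "size of the distortion" as the
#' extent radius, which keeps every level (including 120 percent) well
#' defined.  The alternative `"mass"` mode sizes the spot to enclose the
#' given fraction of the field's total kernel-weight mass (clamped to 1),
#' for which scales above 1 fall back to full support coverage.
#'
#' @param field A non-empty [distortion_field()].
#' @param scale Non-negative sizing fraction; 0 yields an empty spot.
#' @param size_mode `"radius"` (default) or `"mass"`.
#' @return An object of class `suppression_spot` with `retinal_center_deg`
#'   (offset from fixation), `radius_deg` and `scale`.
#' @export
make_spot <- function(field, scale, size_mode = c("radius", "mass")) {
  stopifnot(inherits(field, "distortion_field"))
  size_mode <- match.arg(size_mode)
  if (!is_number(scale) || scale < 0) stopf("'scale' must be >= 0")
  if (n_kernels(field) == 0) stopf("cannot size a spot for an empty field")
  ext <- distortion_extent(field)
  radius <- if (size_mode == "radius") {
    scale * ext$radius
  } else if (scale == 0) {
    0
  } else if (scale >= 1) {
    ext$radius
  } else {
    mass_radius(field, ext, scale)
  }
  structure(list(retinal_center_deg = ext$center, radius_deg = radius,
                 scale = scale, size_mode = size_mode),
            class = "suppression_spot")
}

# Radius about the extent center enclosing `frac` of the total kernel
# weight mass, by radial quadrature on a fine polar grid.
mass_radius <- function(field, ext, frac) {
  radii <- seq(0, ext$radius, length.out = 400L)[-1]
  angles <- seq(0, 2 * pi, length.out = 129L)[-1]
  pts <- cbind(ext$center[1] + rep(radii, each = length(angles)) * cos(angles),
               ext$center[2] + rep(radii, each = length(angles)) * sin(angles))
  wt <- rep(0, nrow(pts))
  for (k in field$kernels) wt <- wt + kernel_weight(k, pts)
  ring <- rowsum(wt, rep(seq_along(radii), each = length(angles)))[, 1] * radii
  cum <- cumsum(ring) / sum(ring)
  radii[which(cum >= frac)[1]]
}

#' Rasterize a suppression spot as a gaze-locked boolean mask
#'
#' The spot sits at a fixed retinal location: its raster position is
#' `gaze + retinal_center`, so shifting gaze by some offset shifts the mask
#' disk by exactly the pixel image of that offset.
#'
#' @param spot A [make_spot()] object.
#' @param gaze_deg Current gaze position, visual-field degrees.
#' @param rs A [raster_spec()].
#' @return Height x width logical matrix; TRUE inside the spot.
#' @export
spot_mask <- function(spot, gaze_deg, rs) {
  stopifnot(inherits(spot, "suppression_spot"), inherits(rs, "raster_spec"))
  gaze_deg <- check_point2(gaze_deg, "gaze_deg")
  h <- rs$height_px; w <- rs$width_px
  if (spot$radius_deg <= 0) return(matrix(FALSE, h, w))
  center <- gaze_deg + spot$retinal_center_deg
  ctr <- pixel_centers_deg(rs)
  dx2 <- (ctr$x - center[1])^2
  dy2 <- (ctr$y - center[2])^2
  outer(dy2, dx2, `+`) <= spot$radius_deg^2
}

#' Apply a suppression mask to an image
#'
#' Masked pixels are set to pure black; all other pixels are returned
#' bit-exact.
#'
#' @param image Numeric matrix or height x width x 3 array.
#' @param mask Logical matrix of the same raster shape.
#' @return Image with masked pixels blacked out.
#' @export
apply_spot <- function(image, mask) {
  dims <- dim(image)
  if (!identical(dim(mask), dims[1:2]))
    stopf("image (%d x %d) and mask (%d x %d) shapes differ",
          dims[1], dims[2], dim(mask)[1], dim(mask)[2])
  if (length(dims) == 2L) {
    image[mask] <- 0
    return(image)
  }
  for (ch in seq_len(dims[3])) {
    plane <- image[, , ch]
    plane[mask] <- 0
    image[, , ch] <- plane
  }
  image
}

#' @export
print.suppression_spot <- function(x, ...) {
  cat(sprintf("<suppression_spot> retinal center (%.3g, %.3g) deg, radius %.3g deg (scale %.3g, %s sizing)\n",
              x$retinal_center_deg[1], x$retinal_center_deg[2], x$radius_deg,
              x$scale, x$size_mode))
  invisible(x)
}
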