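#' Raster geometry of a per-eye display
#'
#' Describes how visual-field coordinates (degrees, x right / y up, fixation
#' at the origin by default) map onto a raster (pixel (0,0) at the top-left
#' corner, pixel centers at half-integer positions).  The conversion is a
#' single uniform affine map: the diagonal field of view is spread over the
#' raster diagonal, and the fixation point lands on the raster center.
#'
#' Defaults mirror a current professional head-mounted display: a 110-degree
#' diagonal field of view on a 1440 x 1600 per-eye panel.
#'
#' @param width_px,height_px Raster size in pixels.
#' @param fov_deg Diagonal field of view in degrees mapped onto the raster
#'   diagonal.
#' @param fixation Visual-field coordinates (degrees) displayed at the
#'   raster center.
#' @return An object of class `raster_spec` with elements `width_px`,
#'   `height_px`, `fov_deg`, `fixation` and the derived `px_per_deg` scale.
#' @examples
#' rs <- raster_spec(192, 192, fov_deg = 192 * sqrt(2) / 8)
#' rs$px_per_deg  # 8 pixels per degree
#' @export
raster_spec <- function(width_px = 1440, height_px = 1600, fov_deg = 110,
                        fixation = c(0, 0)) {
  if (!is_number(width_px) || width_px < 1 || width_px != round(width_px))
    stopf("'width_px' must be a positive integer")
  if (!is_number(height_px) || height_px < 1 || height_px != round(height_px))
    stopf("'height_px' must be a positive integer")
  if (!is_number(fov_deg) || fov_deg <= 0)
    stopf("'fov_deg' must be a positive real")
  fixation <- check_point2(fixation, "fixation")
  structure(list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    fov_deg = as.numeric(fov_deg),
    fixation = fixation,
    px_per_deg = sqrt(width_px^2 + height_px^2) / fov_deg
  ), class = "raster_spec")
}

#' Convert between visual-field degrees and raster pixels
#'
#' `deg_to_px()` maps points in visual-field degrees to continuous raster
#' positions (pixel units; the center of 1-based pixel `(row j, col i)` is at
#' `(i - 0.5, j - 0.5)`).  `px_to_deg()` is its exact inverse.
#'
#' @param rs A [raster_spec()].
#' @param points A 2-vector or n x 2 matrix of points.
#' @return An n x 2 matrix of converted points.
#' @export
deg_to_px <- function(rs, points) {
  stopifnot(inherits(rs, "raster_spec"))
  p <- as_points(points)
  s <- rs$px_per_deg
  cbind(rs$width_px / 2 + (p[, 1] - rs$fixation[1]) * s,
        rs$height_px / 2 - (p[, 2] - rs$fixation[2]) * s)
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(rs, points) {
  stopifnot(inherits(rs, "raster_spec"))
  p <- as_points(points)
  s <- rs$px_per_deg
  cbind(rs$fixation[1] + (p[, 1] - rs$width_px / 2) / s,
        rs$fixation[2] + (rs$height_px / 2 - p[, 2]) / s)
}

# Degree coordinates of all pixel centers: list(x = length-w vector of
# column coordinates, y = length-h vector of row coordinates).
pixel_centers_deg <- function(rs) {
  s <- rs$px_per_deg
  px <- seq_len(rs$width_px) - 0.5
  py <- seq_len(rs$height_px) - 0.5
  list(x = rs$fixation[1] + (px - rs$width_px / 2) / s,
       y = rs$fixation[2] + (rs$height_px / 2 - py) / s)
}

#' @export
print.raster_spec <- function(x, ...) {
  cat(sprintf("<raster_spec> %d x %d px, fov %.4g deg diagonal (%.4g px/deg), fixation (%.3g, %.3g)\n",
              x$width_px, x$height_px, x$fov_deg, x$px_per_deg,
              x$fixation[1], x$fixation[2]))
  invisible(x)
}
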