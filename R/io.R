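#' Serialize a distortion field as a YAML or JSON template
#'
#' Templates store the `eye` label and one record per kernel with exactly
#' the kernel field names: `center`, `sigma_deg`, `luminance_loss`,
#' `rotation_strength_rad`, `radial_stretch`, `boundary_alpha`.  The format
#' is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param field A [distortion_field()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_template()` returns `path` invisibly; `read_template()`
#'   returns a [distortion_field()].
#' @export
write_template <- function(field, path) {
  stopifnot(inherits(field, "distortion_field"))
  obj <- list(eye = field$eye,
              kernels = lapply(field$kernels, function(k)
                list(center = as.numeric(k$center),
                     sigma_deg = k$sigma_deg,
                     luminance_loss = k$luminance_loss,
                     rotation_strength_rad = k$rotation_strength_rad,
                     radial_stretch = k$radial_stretch,
                     boundary_alpha = k$boundary_alpha)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stopf("unsupported template extension '.%s' (use .yaml or .json)", ext)
  }
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stopf("unsupported template extension '.%s' (use .yaml or .json)", ext)
  }
  if (is.null(obj$eye)) stopf("template is missing the 'eye' field")
  kernels <- lapply(obj$kernels, function(k)
    make_kernel(center = unlist(k$center), sigma_deg = k$sigma_deg,
                luminance_loss = k$luminance_loss,
                rotation_strength_rad = k$rotation_strength_rad,
                radial_stretch = k$radial_stretch,
                boundary_alpha = k$boundary_alpha))
  distortion_field(kernels, eye = obj$eye)
}

#' Read and write raster images as PNG
#'
#' Thin wrappers over the `png` package; images are numeric matrices (gray)
#' or height x width x 3 arrays (RGB) with values in \[0, 1\].
#'
#' @param image Image matrix or array.
#' @param path File path.
#' @return `read_image_png()` returns the image (alpha channels dropped);
#'   `write_image_png()` returns `path` invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1]
  img
}

#' Display a distortion field as a warped Amsler grid
#'
#' Renders the Amsler grid, warps it through the field's displacement and
#' luminance maps and draws the result with base graphics.
#'
#' @param x A [distortion_field()].
#' @param rs A [raster_spec()].
#' @param gs A [grid_spec()].
#' @param ... Unused.
#' @return The warped image, invisibly.
#' @export
plot.distortion_field <- function(x, rs = study_raster(), gs = grid_spec(),
                                  ...) {
  maps <- render_maps(x, rs)
  img <- warp_image(render_amsler(gs, rs)$image, maps)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = rs$height_px / rs$width_px)
  graphics::rasterImage(grDevices::as.raster(clamp(img, 0, 1)), 0, 0, 1, 1)
  graphics::title(sprintf("%s eye, %d kernel(s)", x$eye, n_kernels(x)))
  invisible(img)
}
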