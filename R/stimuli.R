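#' Amsler-grid stimulus specification
#'
#' The classical Amsler geometry is a 20 x 20 degree square grid of
#' 0.5-degree cells centered on fixation; pitch, extent, line width and
#' chromaticity are all adjustable to permit finer grids, and diagonal
#' lines through fixation can be drawn to reinforce the fixation point when
#' central vision loss makes it hard to find.
#'
#' @param pitch_deg Cell size in degrees (> 0).
#' @param line_width_px Line width in pixels (positive integer).
#' @param line_chroma,background_chroma RGB triples in \[0, 1\]; must differ.
#' @param diagonals Draw the two diagonals through fixation?
#' @param fixation_marker Draw a filled fixation disk?
#' @param extent_deg Side length of the grid square, degrees.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(pitch_deg = 0.5, line_width_px = 1,
                      line_chroma = c(0, 0, 0), background_chroma = c(1, 1, 1),
                      diagonals = TRUE, fixation_marker = TRUE,
                      extent_deg = 20) {
  if (!is_number(pitch_deg) || pitch_deg <= 0) stopf("'pitch_deg' must be > 0")
  if (!is_number(line_width_px) || line_width_px < 1 ||
      line_width_px != round(line_width_px))
    stopf("'line_width_px' must be a positive integer")
  if (length(line_chroma) != 3 || length(background_chroma) != 3 ||
      any(line_chroma < 0 | line_chroma > 1) ||
      any(background_chroma < 0 | background_chroma > 1))
    stopf("chroma values must be RGB triples in [0, 1]")
  if (all(line_chroma == background_chroma))
    stopf("line and background chroma must differ")
  if (!is_number(extent_deg) || extent_deg <= 0) stopf("'extent_deg' must be > 0")
  structure(list(pitch_deg = pitch_deg, line_width_px = as.integer(line_width_px),
                 line_chroma = as.numeric(line_chroma),
                 background_chroma = as.numeric(background_chroma),
                 diagonals = isTRUE(diagonals),
                 fixation_marker = isTRUE(fixation_marker),
                 extent_deg = extent_deg),
            class = "grid_spec")
}

#' Render an Amsler grid
#'
#' Draws a square grid centered on fixation (with optional diagonals and a
#' fixation marker) and returns both the RGB image and the logical mask of
#' line pixels.  A pixel belongs to a line when its center lies within half
#' a line width of the line's geometric position.  Rendering is
#' deterministic.
#'
#' @param gs A [grid_spec()].
#' @param rs A [raster_spec()]; the grid pitch must be below the field of
#'   view.
#' @return List with `image` (height x width x 3 array) and `line_mask`
#'   (height x width logical matrix).
#' @export
render_amsler <- function(gs, rs) {
  stopifnot(inherits(gs, "grid_spec"), inherits(rs, "raster_spec"))
  if (gs$pitch_deg >= rs$fov_deg) stopf("grid pitch must be smaller than the field of view")
  h <- rs$height_px; w <- rs$width_px
  s <- rs$px_per_deg
  ctr <- pixel_centers_deg(rs)
  xr <- ctr$x - rs$fixation[1]           # column coords relative to fixation
  yr <- ctr$y - rs$fixation[2]           # row coords relative to fixation
  half <- gs$extent_deg / 2
  tol <- 1e-9
  band <- gs$line_width_px / 2 + tol     # half line width, px
  mask <- matrix(FALSE, h, w)

  nline <- floor(half / gs$pitch_deg + tol)
  offsets <- (-nline:nline) * gs$pitch_deg
  rows_in <- which(abs(yr) <= half + tol)
  cols_in <- which(abs(xr) <= half + tol)
  for (o in offsets) {
    vcols <- which(abs(xr - o) * s <= band)
    if (length(vcols)) mask[rows_in, vcols] <- TRUE
    hrows <- which(abs(yr - o) * s <= band)
    if (length(hrows)) mask[hrows, cols_in] <- TRUE
  }

  if (gs$diagonals || gs$fixation_marker) {
    X <- matrix(xr, h, w, byrow = TRUE)
    Y <- matrix(yr, h, w)
    inside <- abs(X) <= half + tol & abs(Y) <= half + tol
    if (gs$diagonals) {
      mask <- mask | (inside & abs(X - Y) / sqrt(2) * s <= band)
      mask <- mask | (inside & abs(X + Y) / sqrt(2) * s <= band)
    }
    if (gs$fixation_marker)
      mask <- mask | (sqrt(X^2 + Y^2) * s <= 2 * gs$line_width_px + tol)
  }

  image <- array(rep(gs$background_chroma, each = h * w), c(h, w, 3L))
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- gs$line_chroma[ch]
    image[, , ch] <- plane
  }
  list(image = image, line_mask = mask)
}

#' Reading-task stimulus specification
#'
#' @param n_words Number of pseudo-Latin words to render.
#' @param n_highlighted Number of highlighted words (<= `n_words`).
#' @param font_px Approximate glyph height in pixels (the bundled 5 x 7
#'   bitmap font is scaled by `round(font_px / 7)`).
#' @param seed Seed for the word generator and highlight choice.
#' @return An object of class `reading_spec`.
#' @export
reading_spec <- function(n_words = 40, n_highlighted = 5, font_px = 7, seed = 1) {
  if (!is_number(n_words) || n_words < 1) stopf("'n_words' must be a positive integer")
  if (!is_number(n_highlighted) || n_highlighted < 1 || n_highlighted > n_words)
    stopf("'n_highlighted' must be a positive integer <= n_words")
  if (!is_number(font_px) || font_px < 4) stopf("'font_px' must be an integer >= 4")
  structure(list(n_words = as.integer(n_words),
                 n_highlighted = as.integer(n_highlighted),
                 font_px = as.integer(font_px), seed = as.integer(seed)),
            class = "reading_spec")
}

# Seeded pseudo-Latin word: 2-4 CV/CVC syllables, so the text carries no
# lexical predictability.
pseudo_latin_words <- function(n) {
  consonants <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vowels <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    syll <- vapply(seq_len(sample(2:4, 1)), function(j) {
      s <- paste0(sample(consonants, 1), sample(vowels, 1))
      if (stats::runif(1) < 0.35) s <- paste0(s, sample(consonants, 1))
      s
    }, character(1))
    paste(syll, collapse = "")
  }, character(1))
}

#' Render a pseudo-Latin reading task
#'
#' Lays out seeded pseudo-Latin words (CV/CVC syllable chains) with the
#' bundled fixed-width bitmap font, wraps lines inside the raster, and marks
#' `n_highlighted` randomly chosen words with a filled translucent box drawn
#' behind the text.  The same seed always yields a byte-identical image.
#'
#' @param spec A [reading_spec()].
#' @param rs A [raster_spec()].
#' @return List with `image` (height x width x 3 array), `highlight_boxes`
#'   (n x 4 matrix of 1-based pixel rectangles: x0, y0, x1, y1),
#'   `words` (character vector) and `highlight_idx`.
#' @export
render_reading_task <- function(spec, rs) {
  stopifnot(inherits(spec, "reading_spec"), inherits(rs, "raster_spec"))
  h <- rs$height_px; w <- rs$width_px
  k <- max(1L, as.integer(round(spec$font_px / 7)))
  cell_w <- 6L * k                      # 5 px glyph + 1 px gap, scaled
  line_h <- 9L * k
  margin <- 2L + k

  words_and_hl <- with_seed(spec$seed, {
    ws <- pseudo_latin_words(spec$n_words)
    list(words = ws, idx = sort(sample.int(spec$n_words, spec$n_highlighted)))
  })
  words <- words_and_hl$words
  hl_idx <- words_and_hl$idx

  image <- array(1, c(h, w, 3L))
  hl_color <- c(1, 1, 0.4)
  boxes <- matrix(NA_integer_, 0L, 4L,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1")))

  # First pass: positions (top-left pixel of each word's glyph row).
  x <- margin + 1L; y <- margin + 1L
  pos <- matrix(0L, spec$n_words, 2L)
  for (i in seq_len(spec$n_words)) {
    width <- nchar(words[i]) * cell_w
    if (x + width - 1L > w - margin) {
      x <- margin + 1L
      y <- y + line_h
    }
    if (y + 7L * k - 1L > h - margin)
      stopf("text overflow: %d words at font_px=%d do not fit a %d x %d raster",
            spec$n_words, spec$font_px, w, h)
    if (x + width - 1L > w - margin)
      stopf("text overflow: word '%s' is wider than the raster", words[i])
    pos[i, ] <- c(x, y)
    x <- x + width + cell_w              # one blank cell between words
  }

  # Highlight boxes behind the words.
  for (i in hl_idx) {
    x0 <- max(1L, pos[i, 1] - k); y0 <- max(1L, pos[i, 2] - k)
    x1 <- min(w, pos[i, 1] + nchar(words[i]) * cell_w - k - 1L + k)
    y1 <- min(h, pos[i, 2] + 7L * k - 1L + k)
    boxes <- rbind(boxes, c(x0, y0, x1, y1))
    for (ch in 1:3)
      image[y0:y1, x0:x1, ch] <- 0.5 * image[y0:y1, x0:x1, ch] + 0.5 * hl_color[ch]
  }

  # Glyphs.
  for (i in seq_len(spec$n_words)) {
    gx <- pos[i, 1]
    for (chr in strsplit(words[i], "")[[1]]) {
      bm <- glyph_bitmap(chr)
      big <- bm[rep(1:7, each = k), rep(1:5, each = k), drop = FALSE]
      rows <- pos[i, 2]:(pos[i, 2] + 7L * k - 1L)
      cols <- gx:(gx + 5L * k - 1L)
      for (ch in 1:3) {
        plane <- image[rows, cols, ch]
        plane[big] <- 0
        image[rows, cols, ch] <- plane
      }
      gx <- gx + cell_w
    }
  }
  list(image = image, highlight_boxes = boxes, words = words,
       highlight_idx = hl_idx)
}

#' Parameter ranges for random metamorphopsia templates
#'
#' Intervals from which [random_metamorphopsia()] draws kernel parameters
#' uniformly.  Defaults emulate moderate clinical metamorphopsia: one to
#' three kernels within 5 degrees of fixation, sub-degree to 2.5-degree
#' sigma, and rotation/stretch amplitudes that keep the warp smoothly
#' invertible.
#'
#' @param n_kernels Integer interval `c(min, max)` for the kernel count.
#' @param sigma_deg,luminance_loss,rotation_strength_rad,radial_stretch,center_eccentricity_deg
#'   Real intervals `c(min, max)`.
#' @param boundary_alpha Fixed support truncation multiplier.
#' @return An object of class `template_ranges`.
#' @export
template_ranges <- function(n_kernels = c(1, 3),
                            sigma_deg = c(0.5, 2.5),
                            luminance_loss = c(0.2, 0.8),
                            rotation_strength_rad = c(-0.5, 0.5),
                            radial_stretch = c(-0.2, 0.25),
                            center_eccentricity_deg = c(0, 5),
                            boundary_alpha = 3) {
  iv <- function(x, name, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      stopf("'%s' must be a non-empty interval c(min, max)", name)
    if (x[1] < lo || x[2] > hi)
      stopf("'%s' interval must lie within [%s, %s]", name, lo, hi)
    as.numeric(x)
  }
  structure(list(
    n_kernels = as.integer(iv(n_kernels, "n_kernels", 1)),
    sigma_deg = iv(sigma_deg, "sigma_deg", lo = 1e-6),
    luminance_loss = iv(luminance_loss, "luminance_loss", 0, 1),
    rotation_strength_rad = iv(rotation_strength_rad, "rotation_strength_rad"),
    radial_stretch = iv(radial_stretch, "radial_stretch", lo = -1 + 1e-6),
    center_eccentricity_deg = iv(center_eccentricity_deg,
                                 "center_eccentricity_deg", 0),
    boundary_alpha = as.numeric(boundary_alpha)
  ), class = "template_ranges")
}

runif_iv <- function(iv) if (iv[1] == iv[2]) iv[1] else stats::runif(1, iv[1], iv[2])

#' Draw a random metamorphopsia template
#'
#' Kernel count and every kernel parameter are drawn uniformly from the
#' intervals in `ranges`; kernel centers are placed at a uniform
#' eccentricity (within its interval) and a uniform polar angle.  Fully
#' reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param ranges A [template_ranges()].
#' @param eye Which eye carries the simulated distortion.
#' @return A [distortion_field()].
#' @export
random_metamorphopsia <- function(seed, ranges = template_ranges(),
                                  eye = c("left", "right")) {
  stopifnot(inherits(ranges, "template_ranges"))
  eye <- match.arg(eye)
  with_seed(seed, {
    nk <- if (ranges$n_kernels[1] == ranges$n_kernels[2]) ranges$n_kernels[1]
          else sample(ranges$n_kernels[1]:ranges$n_kernels[2], 1)
    kernels <- lapply(seq_len(nk), function(i) {
      ecc <- runif_iv(ranges$center_eccentricity_deg)
      ang <- stats::runif(1, 0, 2 * pi)
      make_kernel(center = ecc * c(cos(ang), sin(ang)),
                  sigma_deg = runif_iv(ranges$sigma_deg),
                  luminance_loss = runif_iv(ranges$luminance_loss),
                  rotation_strength_rad = runif_iv(ranges$rotation_strength_rad),
                  radial_stretch = runif_iv(ranges$radial_stretch),
                  boundary_alpha = ranges$boundary_alpha)
    })
    distortion_field(kernels, eye = eye)
  })
}

#' Scale the amplitude intervals of template ranges
#'
#' Multiplies the luminance-loss, rotation and stretch intervals by `m`,
#' leaving geometry (kernel count, sigma, eccentricity, boundary) unchanged.
#' Used to build graded severity conditions.
#'
#' @param ranges A [template_ranges()].
#' @param m Non-negative multiplier.
#' @return A [template_ranges()].
#' @export
scale_ranges <- function(ranges, m) {
  stopifnot(inherits(ranges, "template_ranges"), is_number(m), m >= 0)
  template_ranges(n_kernels = ranges$n_kernels,
                  sigma_deg = ranges$sigma_deg,
                  luminance_loss = clamp(ranges$luminance_loss * m, 0, 1),
                  rotation_strength_rad = ranges$rotation_strength_rad * m,
                  radial_stretch = clamp(ranges$radial_stretch * m, -0.999, Inf),
                  center_eccentricity_deg = ranges$center_eccentricity_deg,
                  boundary_alpha = ranges$boundary_alpha)
}

#' Strongest template admitted by a set of ranges
#'
#' Deterministic field with the maximum kernel count, maximal sigma and
#' amplitude magnitudes, kernels spread evenly at the midpoint eccentricity.
#' Used to calibrate the reference metric mapped to the top of the 0-5
#' scale.
#'
#' @param ranges A [template_ranges()].
#' @param eye Eye label.
#' @return A [distortion_field()].
#' @export
strongest_template <- function(ranges, eye = "left") {
  stopifnot(inherits(ranges, "template_ranges"))
  maxabs <- function(iv) iv[which.max(abs(iv))]
  nk <- ranges$n_kernels[2]
  ecc <- mean(ranges$center_eccentricity_deg)
  kernels <- lapply(seq_len(nk), function(i) {
    ang <- 2 * pi * (i - 1) / nk
    make_kernel(center = ecc * c(cos(ang), sin(ang)),
                sigma_deg = ranges$sigma_deg[2],
                luminance_loss = ranges$luminance_loss[2],
                rotation_strength_rad = maxabs(ranges$rotation_strength_rad),
                radial_stretch = maxabs(ranges$radial_stretch),
                boundary_alpha = ranges$boundary_alpha)
  })
  distortion_field(kernels, eye = eye)
}
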