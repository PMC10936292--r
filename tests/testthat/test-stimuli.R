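test_that("Amsler rendering matches an independent per-pixel rasterizer", {
  rs <- rs_test()
  gs <- gs_test()
  out <- render_amsler(gs, rs)
  oracle <- oracle_amsler_mask(gs, rs)
  expect_identical(out$line_mask, oracle)
  expect_gt(sum(out$line_mask), 0)
})

test_that("diagonals pass through fixation and chroma edits stay on lines", {
  rs <- rs_test()
  gs <- gs_test()
  out <- render_amsler(gs, rs)
  # pixels on the two raster diagonals through fixation are line-colored:
  # with fixation at the pixel corner (48, 48), one diagonal runs along
  # i == j and the other along i + j == 97 (1-based indices)
  for (o in c(-10, -3, 0, 3, 10)) {
    expect_true(out$line_mask[48 + o, 48 + o])
    expect_true(out$line_mask[49 - o, 48 + o])
  }
  # changing line chroma changes exactly the masked pixels
  gs_red <- grid_spec(extent_deg = 10, line_chroma = c(1, 0, 0))
  out_red <- render_amsler(gs_red, rs)
  expect_identical(out_red$line_mask, out$line_mask)
  diffpix <- out_red$image != out$image
  expect_true(all(which(diffpix[, , 2]) %in% which(out$line_mask)))
  same <- !out$line_mask
  expect_identical(out_red$image[, , 2][same], out$image[, , 2][same])
})

test_that("the square grid with diagonals is 90-degree rotation symmetric", {
  # odd raster with integer-pixel pitch puts every line on pixel centers
  rs <- raster_spec(101, 101, fov_deg = 101 * sqrt(2) / 8)
  gs <- grid_spec(extent_deg = 10, diagonals = TRUE)
  m <- render_amsler(gs, rs)$line_mask
  rot90 <- function(x) t(x[nrow(x):1, ])
  expect_identical(rot90(m), m)
  expect_identical(rot90(rot90(m)), m)
})

test_that("reading task rendering is seeded and deterministic", {
  rs <- rs_test()
  spec <- reading_spec(n_words = 12, n_highlighted = 3, font_px = 7, seed = 7)
  a <- render_reading_task(spec, rs)
  b <- render_reading_task(spec, rs)
  expect_identical(a$image, b$image)
  expect_identical(a$highlight_boxes, b$highlight_boxes)
  c2 <- render_reading_task(reading_spec(12, 3, 7, seed = 8), rs)
  expect_false(identical(a$image, c2$image))
})

test_that("reading task renders every word with in-bounds highlight boxes", {
  rs <- raster_spec(256, 256, fov_deg = 256 * sqrt(2) / 8)
  spec <- reading_spec(n_words = 50, n_highlighted = 6, font_px = 7, seed = 1)
  out <- render_reading_task(spec, rs)
  expect_length(out$words, 50)
  expect_identical(nrow(out$highlight_boxes), 6L)
  expect_true(all(out$highlight_boxes[, c(1, 3)] >= 1 &
                    out$highlight_boxes[, c(1, 3)] <= rs$width_px))
  expect_true(all(out$highlight_boxes[, c(2, 4)] >= 1 &
                    out$highlight_boxes[, c(2, 4)] <= rs$height_px))
  # the glyphs actually darken pixels inside each box
  for (i in seq_len(nrow(out$highlight_boxes))) {
    b <- out$highlight_boxes[i, ]
    expect_lt(min(out$image[b[2]:b[4], b[1]:b[3], 1]), 0.5)
  }
})

test_that("oversized text raises an overflow error", {
  rs <- raster_spec(48, 32, fov_deg = 48 * sqrt(2) / 8)
  expect_error(render_reading_task(reading_spec(n_words = 200, font_px = 14), rs),
               "overflow")
})

test_that("random templates are reproducible and respect their ranges", {
  ranges <- template_ranges()
  f1 <- random_metamorphopsia(123, ranges)
  f2 <- random_metamorphopsia(123, ranges)
  expect_identical(f1, f2)

  for (s in 1:200) {
    f <- random_metamorphopsia(s, ranges)
    nk <- length(f$kernels)
    expect_true(nk >= ranges$n_kernels[1] && nk <= ranges$n_kernels[2])
    for (k in f$kernels) {
      expect_true(k$sigma_deg >= ranges$sigma_deg[1] &&
                    k$sigma_deg <= ranges$sigma_deg[2])
      expect_true(k$luminance_loss >= ranges$luminance_loss[1] &&
                    k$luminance_loss <= ranges$luminance_loss[2])
      expect_true(k$rotation_strength_rad >= ranges$rotation_strength_rad[1] &&
                    k$rotation_strength_rad <= ranges$rotation_strength_rad[2])
      expect_true(k$radial_stretch >= ranges$radial_stretch[1] &&
                    k$radial_stretch <= ranges$radial_stretch[2])
      ecc <- sqrt(sum(k$center^2))
      expect_true(ecc >= ranges$center_eccentricity_deg[1] - 1e-12 &&
                    ecc <= ranges$center_eccentricity_deg[2] + 1e-12)
    }
  }
})

test_that("degenerate point ranges yield the exact specified kernel", {
  ranges <- template_ranges(n_kernels = c(1, 1), sigma_deg = c(1.5, 1.5),
                            luminance_loss = c(0.4, 0.4),
                            rotation_strength_rad = c(0.25, 0.25),
                            radial_stretch = c(-0.1, -0.1),
                            center_eccentricity_deg = c(0, 0))
  f <- random_metamorphopsia(99, ranges)
  k <- f$kernels[[1]]
  expect_equal(k$center, c(0, 0))
  expect_identical(k$sigma_deg, 1.5)
  expect_identical(k$luminance_loss, 0.4)
  expect_identical(k$rotation_strength_rad, 0.25)
  expect_identical(k$radial_stretch, -0.1)
})
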