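test_that("binocular composite fills in masked pixels from the healthy eye", {
  set.seed(5)
  aff <- matrix(stats::runif(64 * 64), 64, 64)
  hea <- matrix(stats::runif(64 * 64), 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[20:40, 10:30] <- TRUE

  none <- matrix(FALSE, 64, 64)
  expect_identical(binocular_composite(aff, hea, none), aff)
  out <- binocular_composite(aff, hea, mask)
  expect_identical(out[mask], hea[mask])
  expect_identical(out[!mask], aff[!mask])
  # monocular mode ignores the healthy image entirely
  expect_identical(binocular_composite(aff, hea, mask, mode = "monocular_affected"),
                   binocular_composite(aff, hea * 0, mask, mode = "monocular_affected"))
  expect_error(binocular_composite(aff, hea[1:10, 1:10], mask), "shapes differ")
})

test_that("grid distortion metric agrees with a map-based evaluation", {
  rs <- rs_test(); gs <- gs_test()
  f <- distortion_field(list(make_kernel(c(-1, 1), 1.2, 0.4, 0.3, 0.1),
                             make_kernel(c(1, -1), 0.8, 0.2, -0.2, 0.15)))
  lm <- render_amsler(gs, rs)$line_mask
  mask <- spot_mask(make_spot(f, 0.25), c(0, 0), rs)
  m <- grid_distortion_metric(f, mask, rs, gs)

  # oracle: dense displacement map, mean |d| in degrees over selected pixels
  maps <- render_maps(f, rs)
  sel <- lm & !mask
  dmag <- sqrt(maps$displacement[, , 1]^2 + maps$displacement[, , 2]^2) /
    rs$px_per_deg
  expect_equal(m, mean(dmag[sel]) / gs$pitch_deg, tolerance = 1e-9)
})

test_that("metric is zero for empty fields and full coverage", {
  rs <- rs_test(); gs <- gs_test()
  expect_identical(grid_distortion_metric(distortion_field(), NULL, rs, gs), 0)
  f <- random_metamorphopsia(4, template_ranges(center_eccentricity_deg = c(0, 2)))
  mask <- spot_mask(make_spot(f, 1.2), c(0, 0), rs)
  expect_identical(grid_distortion_metric(f, mask, rs, gs), 0)
})

test_that("metric is non-increasing across the protocol suppression levels", {
  rs <- study_raster(); gs <- grid_spec()
  lm <- render_amsler(gs, rs)$line_mask
  ranges <- template_ranges()
  for (s in 1:10) {
    f <- random_metamorphopsia(s, ranges)
    m <- vapply(c(0, 0.25, 0.90, 1.20), function(sc) {
      mask <- if (sc == 0) NULL else spot_mask(make_spot(f, sc), c(0, 0), rs)
      grid_distortion_metric(f, mask, rs, gs, line_mask = lm)
    }, numeric(1))
    expect_true(all(diff(m) <= 1e-12), label = sprintf("seed %d monotone", s))
    expect_identical(m[4], 0)
  }
})

test_that("to_score rounds half-up onto the 0..5 scale", {
  expect_identical(to_score(0, 1), 0L)
  expect_identical(to_score(2, 1), 5L)
  expect_identical(to_score(1, 1), 5L)
  expect_identical(to_score(0.5, 1), 3L)  # round(2.5) half-up
  expect_identical(to_score(0.09, 1), 0L)
  expect_identical(to_score(0.1, 1), 1L)
  m <- seq(0, 2, by = 0.01)
  expect_true(all(diff(to_score(m, 1)) >= 0))
  expect_error(to_score(1, 0), "ref_metric")
})

test_that("score calibration maps the strongest template to 5, empty to 0", {
  rs <- study_raster(); gs <- grid_spec()
  ref <- default_ref_metric(template_ranges(), rs, gs)
  expect_identical(to_score(grid_distortion_metric(
    strongest_template(template_ranges()), NULL, rs, gs), ref), 5L)
  expect_identical(to_score(grid_distortion_metric(
    distortion_field(), NULL, rs, gs), ref), 0L)
})

test_that("legibility scoring follows the boxed-pixel residual", {
  rs <- rs_test()
  boxes <- rbind(c(40, 40, 60, 60))
  expect_identical(legibility_score(distortion_field(), NULL, boxes, rs, 1), 0L)
  # a strong kernel centered in the box saturates the scale
  f <- field1(rho = 0.5, s = 0.2, sigma = 1.5, center = c(0.25, -0.25))
  m <- reading_metric(f, NULL, boxes, rs)
  expect_identical(legibility_score(f, NULL, boxes, rs, ref_metric = m), 5L)
  # a fully covering spot restores legibility
  mask <- spot_mask(make_spot(f, 1.2), c(0, 0), rs)
  expect_identical(legibility_score(f, mask, boxes, rs, 1), 0L)
  expect_error(reading_metric(f, NULL, rbind(c(0, 1, 10, 10)), rs), "within")
})

test_that("synthetic participants are reproducible and bounded", {
  # zero noise, zero lapse: responses equal to_score exactly
  p0 <- synthetic_participant(0, 0, seed = 1)
  for (m in c(0, 0.3, 0.5, 2)) {
    expect_identical(participant_response(p0, m, 1), to_score(m, 1))
  }
  # noisy responses stay in 0..5 and replay identically per seed
  draw_seq <- function(seed) {
    p <- synthetic_participant(1.5, 0.1, seed = seed)
    vapply(rep(c(0.2, 0.5, 0.9), 10), function(m)
      participant_response(p, m, 1), integer(1))
  }
  a <- draw_seq(42); b <- draw_seq(42); c2 <- draw_seq(43)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_true(all(a >= 0 & a <= 5))
  # the participant stream does not disturb the caller's RNG
  set.seed(9); x1 <- stats::runif(1)
  set.seed(9); invisible(draw_seq(1)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})
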