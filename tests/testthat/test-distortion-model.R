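test_that("displacement vanishes for zero amplitudes and outside supports", {
  f <- field1(rho = 0, s = 0, lambda = 0.7)
  pts <- rbind(c(0, 0), c(1, 1), c(-3, 2), c(5.9, 0))
  expect_identical(displacement_at(f, pts), matrix(0, 4, 2))

  f2 <- field1(rho = 0.4, s = 0.2)
  outside <- rbind(c(6.01, 0), c(0, -7), c(10, 10))
  expect_identical(displacement_at(f2, outside), matrix(0, 3, 2))
})

test_that("displacement matches an independent scalar evaluation", {
  k <- list(center = c(0.5, -1), sigma = 1.5, rho = 0, s = 0.2, alpha = 3)
  f <- distortion_field(list(make_kernel(k$center, k$sigma, 0, k$rho, k$s,
                                         k$alpha)))
  # radial-only kernel: at r = sigma on the +x axis the displacement is
  # parallel to x with the closed-form magnitude
  p <- k$center + c(k$sigma, 0)
  d <- displacement_at(f, p)[1, ]
  expect_equal(d[2], 0)
  expect_equal(d[1], k$sigma * k$s * exp(-1 / 2))

  # 10 sample points against the scalar oracle, radial and rotational
  set.seed(7)
  ks <- list(center = c(-1, 2), sigma = 1.2, rho = 0.35, s = -0.15, alpha = 3)
  fs <- distortion_field(list(make_kernel(ks$center, ks$sigma, 0.3, ks$rho,
                                          ks$s, ks$alpha)))
  for (i in 1:10) {
    p <- ks$center + stats::runif(2, -4, 4)
    expect_equal(displacement_at(fs, p)[1, ],
                 oracle_offset(ks$center, ks$sigma, ks$rho, ks$s, ks$alpha, p),
                 tolerance = 1e-12)
  }
})

test_that("rendered maps agree with pointwise evaluation and compose gains", {
  rs <- rs_test()
  f <- distortion_field(list(
    make_kernel(c(-1, 1), 1.5, 0.5, 0.3, 0.1),
    make_kernel(c(2, -0.5), 0.8, 0.2, -0.2, 0.15)))
  maps <- render_maps(f, rs)

  set.seed(11)
  ij <- cbind(sample.int(rs$height_px, 20, TRUE), sample.int(rs$width_px, 20, TRUE))
  pts <- px_to_deg(rs, cbind(ij[, 2] - 0.5, ij[, 1] - 0.5))
  d <- displacement_at(f, pts) * rs$px_per_deg
  expect_lt(max(abs(d[, 1] - maps$displacement[, , 1][ij])), 1e-9)
  expect_lt(max(abs(-d[, 2] - maps$displacement[, , 2][ij])), 1e-9)

  # empty field: zero displacement, unit gain
  empty <- render_maps(distortion_field(), rs)
  expect_identical(max(abs(empty$displacement)), 0)
  expect_identical(range(empty$luminance), c(1, 1))

  # coincident kernels with lambda = 0.5 each: multiplicative center gain
  f2 <- distortion_field(list(make_kernel(c(0, 0), 1, 0.5),
                              make_kernel(c(0, 0), 1, 0.5)))
  g <- luminance_gain_at <- metamorphsim:::luminance_gain_at(f2, c(0, 0))
  expect_equal(g, 0.25)
})

test_that("kernel order does not affect rasterized output", {
  rs <- rs_test()
  ks <- list(make_kernel(c(-1, 1), 1.5, 0.5, 0.3, 0.1),
             make_kernel(c(2, -0.5), 0.8, 0.2, -0.2, 0.15),
             make_kernel(c(0, -2), 1.1, 0.7, 0.1, -0.1))
  m1 <- render_maps(distortion_field(ks), rs)
  m2 <- render_maps(distortion_field(ks[c(3, 1, 2)]), rs)
  expect_lt(max(abs(m1$displacement - m2$displacement)), 1e-12)
  expect_lt(max(abs(m1$luminance - m2$luminance)), 1e-12)
})

test_that("distortion is exactly local to kernel supports with bounded gain", {
  rs <- rs_test()
  f <- distortion_field(list(make_kernel(c(-2, 1), 0.9, 0.6, 0.4, 0.2),
                             make_kernel(c(2, -2), 0.7, 0.3, -0.3, -0.1)))
  maps <- render_maps(f, rs)
  W <- field_weight_matrix(f, rs)
  ctr <- metamorphsim:::pixel_centers_deg(rs)
  # brute-force support: distance to each kernel center vs alpha * sigma
  support <- matrix(FALSE, rs$height_px, rs$width_px)
  for (k in f$kernels) {
    for (j in seq_len(rs$height_px)) {
      r <- sqrt((ctr$x - k$center[1])^2 + (ctr$y[j] - k$center[2])^2)
      support[j, ] <- support[j, ] | r < k$boundary_alpha * k$sigma_deg
    }
  }
  dmag <- sqrt(maps$displacement[, , 1]^2 + maps$displacement[, , 2]^2)
  expect_identical(max(dmag[!support]), 0)
  expect_identical(min(maps$luminance[!support]), 1)
  # luminance bounds: within [1 - lambda_max, 1] everywhere
  lmax <- max(vapply(f$kernels, function(k) k$luminance_loss, numeric(1)))
  expect_true(all(maps$luminance >= 1 - lmax - 1e-12))
  expect_true(all(maps$luminance <= 1))
  expect_identical(max(W[!support]), 0)
})
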