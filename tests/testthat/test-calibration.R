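r1 <- template_ranges(n_kernels = c(1, 1))

test_that("contralateral reconstruction recovers a remembered kernel", {
  # empty target: fitted amplitudes collapse to ~0
  p <- synthetic_participant(seed = 1)
  r0 <- reconstruct_contralateral(distortion_field(), p, r1, budget = 400)
  k0 <- r0$fitted_field$kernels[[1]]
  expect_lt(abs(k0$rotation_strength_rad), 0.02)
  expect_lt(abs(k0$radial_stretch), 0.02)
  expect_lt(k0$luminance_loss, 0.25)
  expect_lt(tail(r0$objective_trace, 1), 0.02)

  # noiseless single-kernel targets: center within 0.5 deg, sigma within 15%
  for (s in 1:20) {
    target <- random_metamorphopsia(s, r1)
    part <- synthetic_participant(seed = s)
    res <- reconstruct_contralateral(target, part, r1)
    kt <- target$kernels[[1]]; kf <- res$fitted_field$kernels[[1]]
    expect_lt(sqrt(sum((kf$center - kt$center)^2)), 0.5)
    expect_lt(abs(kf$sigma_deg - kt$sigma_deg) / kt$sigma_deg, 0.15)
    expect_true(all(diff(res$objective_trace) <= 0))
    expect_lte(res$n_queries, 800)
  }
})

test_that("corrective assessment drives the reported score to zero", {
  # empty affected field: single baseline query, trivial correction
  p <- synthetic_participant(seed = 1)
  r0 <- corrective_assessment(distortion_field(), p, r1)
  expect_identical(r0$n_queries, 1L)
  expect_identical(r0$final_score, 0L)
  expect_identical(n_kernels(r0$fitted_field), 0L)

  rs <- study_raster(); gs <- grid_spec()
  pts <- metamorphsim:::calibration_points(rs, gs)
  for (s in 1:10) {
    f <- random_metamorphopsia(s, r1)
    part <- synthetic_participant(seed = s)
    res <- corrective_assessment(f, part, r1)
    expect_identical(res$final_score, 0L)
    expect_true(all(diff(res$objective_trace) <= 0))
    # within 2x of the oracle-seeded parametric fit
    fit <- fit_corrective_field(f, rs)
    m_cal <- metamorphsim:::composed_metric_at(res$fitted_field, f, pts,
                                               gs$pitch_deg)
    m_fit <- metamorphsim:::composed_metric_at(fit, f, pts, gs$pitch_deg)
    expect_lt(m_cal, 2 * m_fit + 1e-9)
  }
})

test_that("the examiner reverses rotation after a worsening report", {
  # hidden clockwise rotation: the initial clockwise corrective step doubles
  # the distortion, so the examiner must reverse; counter-clockwise hidden
  # rotation is cancelled by the first clockwise step and needs no reversal
  hid_ccw <- distortion_field(list(make_kernel(c(1, 0), 1.5, 0, 0.4, 0)))
  p1 <- synthetic_participant(seed = 1, hidden_field = hid_ccw)
  res1 <- macular_hole_procedure(p1, r1)
  expect_false(res1$log$rotation_reversed)
  expect_identical(res1$final_score, 0L)

  hid_cw <- distortion_field(list(make_kernel(c(1, 0), 1.5, 0, -0.4, 0)))
  p2 <- synthetic_participant(seed = 1, hidden_field = hid_cw)
  res2 <- macular_hole_procedure(p2, r1)
  expect_true(res2$log$rotation_reversed)
  expect_identical(res2$final_score, 0L)
})

test_that("the examiner procedure recovers hidden kernels to score zero", {
  # empty hidden field: terminates immediately
  p0 <- synthetic_participant(seed = 1, hidden_field = distortion_field())
  r0 <- macular_hole_procedure(p0, r1)
  expect_identical(r0$final_score, 0L)
  expect_identical(r0$n_queries, 1L)

  for (s in 1:20) {
    hid <- random_metamorphopsia(s, r1)
    p <- synthetic_participant(seed = s, hidden_field = hid)
    res <- macular_hole_procedure(p, r1)
    expect_identical(res$final_score, 0L)
    expect_true(res$converged)
    # localized center within one center-step of the hidden center
    expect_lt(sqrt(sum((res$log$center - hid$kernels[[1]]$center)^2)), 0.25)
    # the red circle covers the hidden support within one radius-step
    needed <- sqrt(sum((res$log$center - hid$kernels[[1]]$center)^2)) +
      3 * hid$kernels[[1]]$sigma_deg
    expect_gte(res$log$radius, needed)
    expect_lte(res$log$radius, needed + 0.25)
    expect_true(all(diff(res$objective_trace) <= 0))
  }
  expect_error(macular_hole_procedure(synthetic_participant(seed = 1), r1),
               "hidden_field")
})

test_that("the examiner procedure tolerates response noise", {
  finals <- vapply(1:20, function(s) {
    p <- synthetic_participant(score_noise_sd = 0.5, seed = s,
                               hidden_field = random_metamorphopsia(s, r1))
    macular_hole_procedure(p, r1)$final_score
  }, integer(1))
  expect_lte(stats::median(finals), 1)
})
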