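small_config <- function(...) {
  protocol_config(n_participants = 3,
                  conditions = list(template_ranges()),
                  seed = 11, ...)
}

test_that("the protocol enumerates participants x conditions x scales x tasks", {
  recs <- run_protocol(small_config())
  expect_identical(nrow(recs), 3L * 1L * 4L * 2L)  # 24 score rows
  expect_setequal(unique(recs$task), c("grid", "reading"))
  expect_identical(sort(unique(recs$suppression_scale)), c(0, 0.25, 0.90, 1.20))
  expect_true(all(recs$score >= 0 & recs$score <= 5))
  expect_true(all(is.na(recs$first_imperceptible_scale) |
                    recs$first_imperceptible_scale %in% recs$suppression_scale))
})

test_that("the default protocol has six severity conditions and four levels", {
  cfg <- protocol_config()
  expect_length(cfg$conditions, 6)
  expect_identical(cfg$suppression_scales, c(0, 0.25, 0.90, 1.20))
  expect_error(protocol_config(suppression_scales = c(0.5, 0.25)),
               "strictly increasing")
})

test_that("protocol output is fully determined by the seed", {
  a <- run_protocol(small_config())
  b <- run_protocol(small_config())
  expect_identical(a, b)
  c2 <- run_protocol(protocol_config(n_participants = 3,
                                     conditions = list(template_ranges()),
                                     seed = 12))
  expect_false(identical(a, c2))

  # byte-for-byte reproducible CSV
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials_csv(a, f1); write_trials_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("suppression suppresses: scores fall with spot size in the study", {
  recs <- run_protocol(protocol_config(n_participants = 6, seed = 1))
  for (task in c("grid", "reading")) {
    means <- chi_square_analysis(recs, task)$level_means
    # qualitative ordering: non-increasing means, elimination at 120%
    expect_true(all(diff(means) <= 1e-12))
    expect_identical(unname(means[4]), 0)
  }
  # the quantized grid means resolve a strict drop up to the 90% level
  gm <- chi_square_analysis(recs, "grid")$level_means
  expect_lt(gm[2], gm[1])
  expect_lt(gm[3], gm[2])
  # every 120% trial is individually imperceptible
  expect_true(all(recs$score[recs$suppression_scale == 1.2] == 0L))
})

test_that("chi-square analysis matches the Pearson formula", {
  # identical score distributions across levels: statistic exactly 0
  recs <- data.frame(participant_id = 1:20, eye = "left", condition_id = 1L,
                     task = "grid",
                     suppression_scale = rep(c(0, 0.25), each = 10),
                     score = rep(rep(c(2L, 4L), 5), 2),
                     first_imperceptible_scale = NA_real_,
                     first_noticed_scale = NA_real_)
  a <- chi_square_analysis(recs, "grid")
  expect_equal(a$statistic, 0)
  expect_equal(as.numeric(a$level_means), c(3, 3))

  # 2x2 concentration: N x perfect association = 20
  expect_equal(chi_square_table(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_identical(chi_square_table(rbind(c(10, 0), c(0, 10)))$df, 1L)

  # 50 random tables against the brute-force sum (O - E)^2 / E
  set.seed(31)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(24, lambda = sample(1:8, 1)), 6, 4)
    if (sum(tab > 0) <= 1 ||
        sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2) next
    expect_lt(abs(chi_square_table(tab)$statistic - chisq_brute(tab)), 1e-9)
  }
  expect_error(chi_square_table(rbind(c(5, 0), c(0, 0))), "degenerate")
})

test_that("trial CSV round-trips losslessly and validates on read", {
  recs <- run_protocol(small_config())
  path <- tempfile(fileext = ".csv")
  write_trials_csv(recs, path)
  back <- read_trials_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))

  # header-only file for an empty record set
  write_trials_csv(recs[0, ], path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_trials_csv(path)), 0L)

  # an out-of-range score is rejected with its line number
  bad <- recs; bad$score[3] <- 7L
  write_trials_csv(bad, path)
  expect_error(read_trials_csv(path), "line 4.*score")
  unlink(path)
})
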