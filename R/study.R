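#' Repeated-measures study protocol configuration
#'
#' Defines the simulated validation protocol: per participant, a random
#' metamorphopsia template is simulated in one randomly chosen eye for each
#' severity condition, dark-spot suppression is applied at ascending scales
#' (default 0, 25, 90 and 120 percent of the distortion extent), and the
#' participant scores perceived distortion on the Amsler grid and
#' legibility of highlighted reading text on 0-5 scales.
#'
#' The six default severity conditions are the base template ranges with
#' amplitude intervals scaled by evenly spaced multipliers 1/6, 2/6, ...,
#' 6/6 (the severity presets are a package choice; only their count is
#' protocol-fixed).
#'
#' @param n_participants Number of synthetic participants.
#' @param conditions List of [template_ranges()] severity presets (default:
#'   six evenly spaced amplitude scalings of `base_ranges`).
#' @param base_ranges Ranges scaled into the default conditions.
#' @param suppression_scales Strictly increasing suppression levels.
#' @param tasks Subset of `c("grid", "reading")`.
#' @param seed Master seed; fully determines the protocol output.
#' @param score_noise_sd,lapse_rate Participant response noise (defaults
#'   noiseless, so scores are deterministic percept functions).
#' @param rs,gs,reading Raster, grid and reading-stimulus specifications.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_participants = 18, conditions = NULL,
                            base_ranges = template_ranges(),
                            suppression_scales = c(0, 0.25, 0.90, 1.20),
                            tasks = c("grid", "reading"), seed = 1,
                            score_noise_sd = 0, lapse_rate = 0,
                            rs = study_raster(), gs = grid_spec(),
                            reading = reading_spec()) {
  if (!is_number(n_participants) || n_participants < 1)
    stopf("'n_participants' must be a positive integer")
  if (is.null(conditions))
    conditions <- lapply(seq_len(6) / 6, function(m) scale_ranges(base_ranges, m))
  if (!is.list(conditions) ||
      !all(vapply(conditions, inherits, TRUE, "template_ranges")))
    stopf("'conditions' must be a list of template_ranges")
  if (length(suppression_scales) < 1 ||
      any(diff(suppression_scales) <= 0) || any(suppression_scales < 0))
    stopf("'suppression_scales' must be non-negative and strictly increasing")
  tasks <- match.arg(tasks, c("grid", "reading"), several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions,
                 suppression_scales = as.numeric(suppression_scales),
                 tasks = tasks, seed = as.integer(seed),
                 score_noise_sd = score_noise_sd, lapse_rate = lapse_rate,
                 rs = rs, gs = gs, reading = reading),
            class = "protocol_config")
}

#' Run the simulated repeated-measures suppression protocol
#'
#' For each participant: a baseline no-distortion check (both scores must be
#' 0), then for each severity condition a random template in one randomly
#' chosen eye, scored at each ascending suppression scale on every task via
#' the synthetic participant.  Per (participant, condition, task) the first
#' suppression scale at which the distortion becomes imperceptible (score
#' 0) is recorded, as is the first scale at which the spot itself becomes
#' noticeable (covers at least one grid-line pixel).  The output is fully
#' reproducible from `config$seed`.
#'
#' @param config A [protocol_config()].
#' @return A data frame of class `trial_records`, one row per
#'   (participant, condition, suppression scale, task) score.
#' @export
run_protocol <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  rs <- config$rs; gs <- config$gs
  amsler <- render_amsler(gs, rs)
  reading <- render_reading_task(config$reading, rs)
  boxes <- reading$highlight_boxes
  box_sel <- boxes_mask(boxes, rs)
  scales <- config$suppression_scales

  # Score-5 references, calibrated once against the strongest condition.
  strongest <- config$conditions[[which.max(vapply(config$conditions, function(r)
    max(abs(r$rotation_strength_rad), abs(r$radial_stretch)), numeric(1)))]]
  ref_grid <- grid_distortion_metric(strongest_template(strongest), NULL, rs, gs,
                                     line_mask = amsler$line_mask)
  ref_reading <- reading_metric(strongest_template(strongest), NULL, boxes, rs)
  ref_reading <- max(ref_reading, 1e-9)

  draws <- with_seed(config$seed, {
    lapply(seq_len(config$n_participants), function(i) list(
      pseed = sample.int(2^31 - 1, 1),
      eyes = sample(c("left", "right"), length(config$conditions), replace = TRUE),
      tseeds = sample.int(2^31 - 1, length(config$conditions))))
  })

  rows <- vector("list", 0L)
  for (i in seq_len(config$n_participants)) {
    part <- synthetic_participant(config$score_noise_sd, config$lapse_rate,
                                  seed = draws[[i]]$pseed)
    # Baseline: the empty field must be imperceptible on both tasks.
    stopifnot(to_score(grid_distortion_metric(
      distortion_field(), NULL, rs, gs, line_mask = amsler$line_mask),
      ref_grid) == 0L)
    for (ci in seq_along(config$conditions)) {
      field <- random_metamorphopsia(draws[[i]]$tseeds[ci],
                                     config$conditions[[ci]],
                                     eye = draws[[i]]$eyes[ci])
      masks <- lapply(scales, function(sc) {
        if (sc == 0) NULL else spot_mask(make_spot(field, sc), c(0, 0), rs)
      })
      noticed <- vapply(seq_along(scales), function(si) {
        !is.null(masks[[si]]) && any(masks[[si]] & amsler$line_mask)
      }, logical(1))
      first_noticed <- if (any(noticed)) scales[which(noticed)[1]] else NA_real_
      for (task in config$tasks) {
        metrics <- vapply(seq_along(scales), function(si) {
          if (task == "grid")
            grid_distortion_metric(field, masks[[si]], rs, gs,
                                   line_mask = amsler$line_mask)
          else
            reading_metric(field, masks[[si]], boxes, rs)
        }, numeric(1))
        ref <- if (task == "grid") ref_grid else ref_reading
        sc_scores <- vapply(metrics, function(m)
          participant_response(part, m, ref), integer(1))
        first_imp <- if (any(sc_scores == 0L)) scales[which(sc_scores == 0L)[1]]
                     else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = i, eye = field$eye, condition_id = ci, task = task,
          suppression_scale = scales, score = sc_scores,
          first_imperceptible_scale = first_imp,
          first_noticed_scale = first_noticed,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_records", "data.frame")
  out
}

#' Chi-square analysis of categorical scores across suppression levels
#'
#' Builds the (score category 0..5) x (suppression level) contingency table
#' for one task, drops empty rows and columns, and computes the Pearson
#' chi-square statistic with df = (r - 1)(c - 1), together with the
#' per-level arithmetic mean scores.  Scores are the categorical responses
#' coded 0 (imperceptible) to 5 (strongest); no multiple-comparison
#' correction is applied.
#'
#' @param records A `trial_records` data frame.
#' @param task `"grid"` or `"reading"`.
#' @return List of class `chi_square_analysis` with `statistic`, `df`,
#'   `p_value`, `level_means` and the contingency `table`.
#' @export
chi_square_analysis <- function(records, task = c("grid", "reading")) {
  task <- match.arg(task)
  recs <- records[records$task == task, , drop = FALSE]
  if (nrow(recs) == 0L) stopf("no records for task '%s'", task)
  if (length(unique(recs$suppression_scale)) < 2L)
    stopf("chi-square analysis needs at least 2 suppression levels")
  tab <- table(factor(recs$score, levels = 0:5),
               factor(recs$suppression_scale))
  res <- chi_square_table(tab)
  means <- c(tapply(recs$score, recs$suppression_scale, mean))
  structure(c(res, list(level_means = means, table = tab, task = task)),
            class = "chi_square_analysis")
}

#' Pearson chi-square test of a contingency table
#'
#' Drops all-zero rows and columns, then computes the Pearson statistic
#' (no continuity correction).  A table whose mass sits in a single cell is
#' degenerate and raises an error; a table with a single surviving row or
#' column has statistic 0 on 0 degrees of freedom (distributions across
#' levels are trivially identical).
#'
#' @param tab A matrix or table of counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_square_table <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (sum(tab > 0) <= 1L)
    stopf("degenerate contingency table: a single nonzero cell")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' @export
print.chi_square_analysis <- function(x, ...) {
  cat(sprintf("Chi-square analysis (%s task): X^2 = %.4g, df = %d, p = %.4g\n",
              x$task, x$statistic, x$df, x$p_value))
  cat("mean score per suppression level:\n")
  print(round(x$level_means, 3))
  invisible(x)
}

#' @export
summary.trial_records <- function(object, ...) {
  for (task in unique(object$task)) {
    print(chi_square_analysis(object, task))
  }
  invisible(object)
}

trial_columns <- c("participant_id", "eye", "condition_id", "task",
                   "suppression_scale", "score", "first_imperceptible_scale",
                   "first_noticed_scale")

#' Write and read trial records as CSV
#'
#' Fixed documented column order
#' (`participant_id,eye,condition_id,task,suppression_scale,score,first_imperceptible_scale,first_noticed_scale`),
#' mandatory header row, lossless round-trip.  `read_trials_csv()` validates
#' each row (eye label, task label, score in 0..5, non-negative scale) and
#' reports the offending CSV line on failure.
#'
#' @param records A `trial_records` data frame.
#' @param path File path.
#' @return `read_trials_csv()` returns a `trial_records` data frame;
#'   `write_trials_csv()` returns `path` invisibly.
#' @export
write_trials_csv <- function(records, path) {
  if (!all(trial_columns %in% names(records)))
    stopf("records are missing columns: %s",
          paste(setdiff(trial_columns, names(records)), collapse = ", "))
  utils::write.csv(records[, trial_columns], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), trial_columns))
    stopf("malformed trials CSV: expected header %s",
          paste(trial_columns, collapse = ","))
  check_row <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad))
      stopf("malformed trials CSV at line %d: %s", bad[1] + 1L, what)
  }
  if (nrow(df)) {
    check_row(df$eye %in% c("left", "right"), "eye must be 'left' or 'right'")
    check_row(df$task %in% c("grid", "reading"), "unknown task")
    check_row(is.finite(df$score) & df$score == round(df$score) &
                df$score >= 0 & df$score <= 5, "score must be an integer in 0..5")
    check_row(is.finite(df$suppression_scale) & df$suppression_scale >= 0,
              "suppression_scale must be >= 0")
    df$score <- as.integer(df$score)
    df$participant_id <- as.integer(df$participant_id)
    df$condition_id <- as.integer(df$condition_id)
  }
  class(df) <- c("trial_records", "data.frame")
  df
}
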