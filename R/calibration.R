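#' Default desk raster for calibration and study runs
#'
#' A 192 x 192 pixel raster at exactly 8 pixels per degree (24 x 24 degrees
#' of field), large enough to contain the default 20-degree Amsler grid
#' with margin while keeping dense map operations cheap.
#'
#' @return A [raster_spec()].
#' @export
study_raster <- function() raster_spec(192, 192, fov_deg = 192 * sqrt(2) / 8)

# Visual-field sample points (degrees) on the Amsler grid lines, thinned to
# at most `max_points`; the percept comparisons of the calibration loops
# are evaluated there.
calibration_points <- function(rs, gs, max_points = 1200) {
  lm <- render_amsler(gs, rs)$line_mask
  idx <- which(lm, arr.ind = TRUE)
  if (nrow(idx) > max_points)
    idx <- idx[seq(1L, nrow(idx), length.out = max_points), , drop = FALSE]
  px_to_deg(rs, cbind(idx[, 2] - 0.5, idx[, 1] - 0.5))
}

#' Reference metric mapped to the top of the 0-5 scale
#'
#' Calibrated once as the grid-distortion metric of the strongest template
#' admitted by the ranges, with no suppression.
#'
#' @param ranges A [template_ranges()].
#' @param rs A [raster_spec()].
#' @param gs A [grid_spec()].
#' @return Positive scalar.
#' @export
default_ref_metric <- function(ranges = template_ranges(), rs = study_raster(),
                               gs = grid_spec()) {
  grid_distortion_metric(strongest_template(ranges), NULL, rs, gs)
}

new_calibration_result <- function(fitted_field, objective_trace, converged,
                                   n_queries, final_score = NA_integer_,
                                   log = list()) {
  structure(list(fitted_field = fitted_field,
                 objective_trace = objective_trace,
                 converged = converged, n_queries = as.integer(n_queries),
                 final_score = final_score, log = log),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d kernel(s) fitted, %d participant queries, converged: %s\n",
              n_kernels(x$fitted_field), x$n_queries, x$converged))
  if (length(x$objective_trace))
    cat(sprintf("  objective: %.4g -> %.4g over %d accepted steps\n",
                x$objective_trace[1], x$objective_trace[length(x$objective_trace)],
                length(x$objective_trace)))
  if (!is.na(x$final_score))
    cat(sprintf("  final reported score: %d\n", x$final_score))
  invisible(x)
}

# Derivative-free coordinate descent.  `query(par)` returns the
# participant-reported objective (each call is one interrogation).  A move
# is accepted only when it strictly improves the best reported value, so
# the accepted trace is non-increasing by construction.  Step sizes halve
# after a sweep with no accepted move; convergence = all steps below
# `min_step`.
coordinate_descent <- function(par0, lower, upper, step0, min_step, query,
                               budget) {
  par <- clamp(par0, lower, upper)
  best <- query(par)
  n <- 1L
  trace <- best
  steps <- step0
  cycle_best <- Inf
  converged <- FALSE
  repeat {
    improved <- FALSE
    for (i in seq_along(par)) {
      if (steps[i] <= 0) next
      for (sgn in c(1, -1)) {
        if (n >= budget) break
        cand <- par
        cand[i] <- clamp(cand[i] + sgn * steps[i], lower[i], upper[i])
        if (cand[i] == par[i]) next
        v <- query(cand)
        n <- n + 1L
        if (v < best - 1e-12) {
          par <- cand; best <- v
          trace <- c(trace, v)
          improved <- TRUE
          break
        }
      }
      if (n >= budget) break
    }
    if (n >= budget) break
    if (!improved) {
      steps <- steps / 2
      if (all(steps < min_step | step0 <= 0)) {
        # Axis-aligned steps stall in curved valleys; while budget remains
        # and the last cycle improved the objective, restart the step
        # schedule from the current point.
        if (best < cycle_best - 1e-12 && n < budget) {
          cycle_best <- best
          steps <- step0 / 4
        } else {
          converged <- TRUE
          break
        }
      }
    }
  }
  list(par = par, objective = best, trace = trace, n_queries = n,
       converged = converged)
}

#' Contralateral reconstruction of a remembered metamorphopsia
#'
#' Emulates the classical procedure in which the participant recreates, in
#' the contralateral eye, the distortion simulated in the test eye.  A
#' candidate field starts from mid-range parameters and is refined by
#' coordinate descent; at each step the participant compares the candidate
#' percept against the remembered target (dissimilarity = mean displacement
#' difference over grid-line points, in grid-pitch units, plus the mean
#' luminance-gain difference), reported with memory noise.
#'
#' @param target_field The simulated [distortion_field()] to reproduce.
#' @param participant A [synthetic_participant()].
#' @param ranges [template_ranges()] bounding the adjustable parameters.
#' @param budget Maximum participant interrogations.
#' @param rs,gs Raster and grid used for the percept comparison.
#' @param lum_weight Weight of the luminance term in the dissimilarity.
#' @return A `calibration_result`.
#' @export
reconstruct_contralateral <- function(target_field, participant,
                                      ranges = template_ranges(), budget = 800,
                                      rs = study_raster(), gs = grid_spec(),
                                      lum_weight = 1) {
  stopifnot(inherits(target_field, "distortion_field"),
            inherits(participant, "synthetic_participant"),
            inherits(ranges, "template_ranges"))
  pts <- calibration_points(rs, gs)
  dT <- displacement_at(target_field, pts)
  gT <- luminance_gain_at(target_field, pts)
  pitch <- gs$pitch_deg

  nk <- max(1L, min(n_kernels(target_field), ranges$n_kernels[2]))
  ecc <- ranges$center_eccentricity_deg[2]
  lower1 <- c(-ecc, -ecc, ranges$sigma_deg[1], ranges$luminance_loss[1],
              ranges$rotation_strength_rad[1], ranges$radial_stretch[1])
  upper1 <- c(ecc, ecc, ranges$sigma_deg[2], ranges$luminance_loss[2],
              ranges$rotation_strength_rad[2], ranges$radial_stretch[2])
  lower <- rep(lower1, nk); upper <- rep(upper1, nk)
  par0 <- rep((lower1 + upper1) / 2, nk)
  step0 <- (upper - lower) / 4
  min_step <- pmax((upper - lower) / 512, 1e-4)

  build <- function(par) {
    kernels <- lapply(seq_len(nk), function(i) {
      p <- par[(i - 1) * 6 + 1:6]
      make_kernel(p[1:2], p[3], p[4], p[5], p[6], ranges$boundary_alpha)
    })
    distortion_field(kernels, eye = target_field$eye)
  }
  query <- function(par) {
    cand <- build(par)
    dC <- displacement_at(cand, pts)
    dis <- mean(sqrt((dC[, 1] - dT[, 1])^2 + (dC[, 2] - dT[, 2])^2)) / pitch
    if (lum_weight > 0)
      dis <- dis + lum_weight * mean(abs(luminance_gain_at(cand, pts) - gT))
    participant_report(participant, dis)
  }
  fit <- coordinate_descent(par0, lower, upper, step0, min_step, query, budget)
  new_calibration_result(build(fit$par), fit$trace, fit$converged,
                         fit$n_queries)
}

# Kernels of a field ordered by decreasing amplitude, recycled/truncated to
# length nk.
field_sorted_kernels <- function(field, nk) {
  ks <- field$kernels[order(-vapply(field$kernels, function(k)
    max(k$luminance_loss, abs(k$rotation_strength_rad), abs(k$radial_stretch)),
    numeric(1)))]
  ks[((seq_len(nk) - 1L) %% length(ks)) + 1L]
}

# Composed residual metric (grid-pitch units) of corrective C followed by
# the pathological field F at sample points.
composed_metric_at <- function(corrective, forward, pts, pitch) {
  dC <- displacement_at(corrective, pts)
  dF <- displacement_at(forward, pts + dC)
  mean(sqrt((dC[, 1] + dF[, 1])^2 + (dC[, 2] + dF[, 2])^2)) / pitch
}

#' Direct corrective assessment on the affected eye
#'
#' The countermeasure procedure: a corrective distortion is drawn on the
#' affected eye itself and its parameters adjusted until the participant
#' reports the composed distortion gone.  The loop only ever queries the
#' affected-eye percept (the contralateral display stays off), using the
#' residual grid metric of corrective-then-pathology as the participant's
#' report.
#'
#' @param affected_field The pathological [distortion_field()].
#' @param participant A [synthetic_participant()].
#' @param ranges [template_ranges()]; rotation and stretch bounds are
#'   widened to their symmetric hulls so every in-range distortion admits an
#'   in-range correction.
#' @param budget Maximum participant interrogations.
#' @param rs,gs Raster and grid for the percept metric.
#' @param ref_metric Metric mapped to score 5 (default: calibrated from
#'   `ranges`).
#' @return A `calibration_result`; `final_score` is the participant's
#'   reported residual score for the fitted correction.
#' @export
corrective_assessment <- function(affected_field, participant,
                                  ranges = template_ranges(), budget = 800,
                                  rs = study_raster(), gs = grid_spec(),
                                  ref_metric = NULL) {
  stopifnot(inherits(affected_field, "distortion_field"),
            inherits(participant, "synthetic_participant"),
            inherits(ranges, "template_ranges"))
  if (is.null(ref_metric)) ref_metric <- default_ref_metric(ranges, rs, gs)
  pts <- calibration_points(rs, gs)
  pitch <- gs$pitch_deg
  empty <- distortion_field(list(), eye = affected_field$eye)
  baseline <- composed_metric_at(empty, affected_field, pts, pitch)
  if (n_kernels(affected_field) == 0L || baseline == 0) {
    return(new_calibration_result(empty, numeric(0), TRUE, n_queries = 1L,
                                  final_score = participant_response(
                                    participant, baseline, ref_metric)))
  }

  nk <- n_kernels(affected_field)
  ecc <- ranges$center_eccentricity_deg[2]
  rho_max <- max(abs(ranges$rotation_strength_rad))
  s_max <- min(max(abs(ranges$radial_stretch)), 0.9)
  # Per kernel: rho, stretch first (they carry the gradient from a
  # zero-amplitude start), then center and sigma.
  lower1 <- c(-rho_max, -s_max, -ecc, -ecc, ranges$sigma_deg[1])
  upper1 <- c(rho_max, s_max, ecc, ecc, ranges$sigma_deg[2])
  lower <- rep(lower1, nk); upper <- rep(upper1, nk)
  # The default corrective patch starts where the participant sees the
  # distortion (its extent center, one patch per kernel support), with zero
  # amplitudes: placement carries no objective gradient until rotation or
  # stretch is non-zero, so a blind mid-field start cannot lock on.
  par0 <- unlist(lapply(field_sorted_kernels(affected_field, nk), function(k)
    c(0, 0, k$center[1], k$center[2],
      clamp(k$sigma_deg, ranges$sigma_deg[1], ranges$sigma_deg[2]))))
  step0 <- (upper - lower) / 4
  min_step <- pmax((upper - lower) / 1024, 1e-4)

  build <- function(par) {
    kernels <- lapply(seq_len(nk), function(i) {
      p <- par[(i - 1) * 5 + 1:5]
      make_kernel(p[3:4], p[5], 0, p[1], p[2], ranges$boundary_alpha)
    })
    distortion_field(kernels, eye = affected_field$eye)
  }
  query <- function(par)
    participant_report(participant,
                       composed_metric_at(build(par), affected_field, pts, pitch))
  fit <- coordinate_descent(par0, lower, upper, step0, min_step, query, budget)
  fitted <- build(fit$par)
  final_metric <- composed_metric_at(fitted, affected_field, pts, pitch)
  new_calibration_result(fitted, fit$trace, fit$converged, fit$n_queries,
                         final_score = participant_response(
                           participant, final_metric, ref_metric))
}

#' Stepwise examiner procedure for a unilateral macular hole
#'
#' Executes the examiner-driven schedule against a participant who
#' perceives a fixed hidden single-kernel distortion: (1) localize the
#' distortion center by directional feedback on a moving dot; (2) grow (or
#' shrink) a circle until the participant reports it fully covers the
#' distorted area; (3) rotate the covered distortion tangentially clockwise,
#' reversing direction after a worsening report; (4) contort radially
#' inward, switching to outward if worse.  Phases 3-4 are repeated while
#' they keep improving, and the procedure terminates once the participant
#' reports the distortion imperceptible (score 0) or the query budget is
#' exhausted.
#'
#' "Worse" and "better" reports follow the sign of the perceived residual
#' metric change with a 2 percent dead-band emulating perceptual
#' indifference.  The loop is deterministic given the participant seed.
#'
#' @param participant A [synthetic_participant()] whose `hidden_field` holds
#'   the single-kernel distortion.
#' @param ranges A [template_ranges()] (supplies the boundary multiplier and
#'   score calibration).
#' @param step_sizes List with `center` and `radius` (degrees), `rotation`
#'   (radians) and `contortion` step sizes.
#' @param budget Maximum participant interrogations.
#' @param rs,gs Raster and grid for the percept metric.
#' @param ref_metric Metric mapped to score 5 (default from `ranges`).
#' @param dead_band Relative indifference band for worse/better reports.
#' @return A `calibration_result`; `log` records the localized center, the
#'   covering radius and whether rotation/contortion direction was reversed.
#' @export
macular_hole_procedure <- function(participant, ranges = template_ranges(),
                                   step_sizes = list(center = 0.25,
                                                     radius = 0.25,
                                                     rotation = 0.05,
                                                     contortion = 0.05),
                                   budget = 300, rs = study_raster(),
                                   gs = grid_spec(), ref_metric = NULL,
                                   dead_band = 0.02) {
  stopifnot(inherits(participant, "synthetic_participant"))
  hidden <- participant$hidden_field
  if (is.null(hidden)) stopf("participant has no hidden_field to assess")
  if (is.null(ref_metric)) ref_metric <- default_ref_metric(ranges, rs, gs)
  pts <- calibration_points(rs, gs)
  pitch <- gs$pitch_deg
  empty <- distortion_field(list(), eye = hidden$eye)
  n <- 0L

  if (n_kernels(hidden) == 0L) {
    return(new_calibration_result(empty, numeric(0), TRUE, 1L,
                                  final_score = participant_response(
                                    participant, 0, ref_metric)))
  }
  if (n_kernels(hidden) != 1L)
    stopf("the macular-hole procedure assumes a single-kernel hidden distortion")
  hk <- hidden$kernels[[1]]
  noise <- function(sd) {
    if (participant$score_noise_sd == 0) 0
    else participant_rng(participant,
                         stats::rnorm(1, 0, sd * participant$score_noise_sd))
  }

  # Phase 1: center localization by directional feedback.
  ctr <- c(0, 0)
  cstep <- step_sizes$center
  repeat {
    n <- n + 1L
    diff <- c(hk$center[1] - ctr[1] + noise(0.1),
              hk$center[2] - ctr[2] + noise(0.1))
    if (all(abs(diff) <= cstep / 2) || n >= budget) break
    ax <- which.max(abs(diff))
    ctr[ax] <- ctr[ax] + sign(diff[ax]) * cstep
  }

  # Phase 2: grow the circle until the participant reports full coverage.
  needed <- sqrt(sum((hk$center - ctr)^2)) + hk$boundary_alpha * hk$sigma_deg
  radius <- step_sizes$radius
  repeat {
    n <- n + 1L
    covered <- radius >= needed * (1 + noise(0.02))
    if (covered || n >= budget) break
    radius <- radius + step_sizes$radius
  }

  sigma_c <- radius / hk$boundary_alpha
  state <- c(rho = 0, s = 0)
  build <- function(st)
    distortion_field(list(make_kernel(ctr, sigma_c, 0, st[["rho"]], st[["s"]],
                                      hk$boundary_alpha)), eye = hidden$eye)
  true_metric <- function(st) composed_metric_at(build(st), hidden, pts, pitch)
  query <- function(st) {
    n <<- n + 1L
    participant_report(participant, true_metric(st))
  }

  trace <- query(state)
  reversed <- c(rotation = FALSE, contortion = FALSE)
  walk <- function(par_name, step, label) {
    dir <- -1                               # clockwise / inward first
    cur <- trace[length(trace)]
    first <- TRUE
    while (n < budget) {
      cand <- state
      cand[[par_name]] <- state[[par_name]] + dir * step
      if (par_name == "s" && cand[["s"]] <= -0.9) break
      v <- query(cand)
      if (v < cur * (1 - dead_band)) {      # better: accept and continue
        state <<- cand
        cur <- v
        trace <<- c(trace, v)
        first <- FALSE
      } else if (first && v > cur * (1 + dead_band)) {
        dir <- -dir                         # worse on the first step: reverse
        reversed[[label]] <<- TRUE
        first <- FALSE
      } else break                          # indifferent or worsening: stop
    }
  }

  score <- function() participant_response(participant, true_metric(state),
                                           ref_metric)
  repeat {
    before <- trace[length(trace)]
    walk("rho", step_sizes$rotation, "rotation")
    walk("s", step_sizes$contortion, "contortion")
    after <- trace[length(trace)]
    if (n >= budget || score() == 0 || after >= before * (1 - dead_band)) break
  }

  final <- score()
  new_calibration_result(build(state), trace, converged = final == 0L,
                         n_queries = n, final_score = final,
                         log = list(center = ctr, radius = radius,
                                    rotation_reversed = reversed[["rotation"]],
                                    contortion_reversed = reversed[["contortion"]]))
}
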