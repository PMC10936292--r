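#' Compose the binocular percept from the two eyes
#'
#' Under binocular viewing with a gaze-locked suppression spot, the healthy
#' eye fills in the suppressed region: masked pixels are taken bit-exact
#' from the healthy eye's image and unmasked pixels from the affected eye's
#' image (worst-case assumption: outside the spot the distorted percept
#' dominates).  In `monocular_affected` mode the contralateral display is
#' off and the healthy image is ignored entirely.
#'
#' @param affected_image,healthy_image Images of identical shape.
#' @param suppression_mask Logical matrix (may be NULL for no suppression).
#' @param mode `"binocular"` or `"monocular_affected"`.
#' @return Composite image, same shape as the inputs.
#' @export
binocular_composite <- function(affected_image, healthy_image,
                                suppression_mask = NULL,
                                mode = c("binocular", "monocular_affected")) {
  mode <- match.arg(mode)
  dims <- dim(affected_image)
  if (mode == "monocular_affected") return(affected_image)
  if (!identical(dim(healthy_image), dims))
    stopf("affected and healthy image shapes differ")
  if (is.null(suppression_mask)) return(affected_image)
  if (!identical(dim(suppression_mask), dims[1:2]))
    stopf("image and mask shapes differ")
  out <- affected_image
  if (length(dims) == 2L) {
    out[suppression_mask] <- healthy_image[suppression_mask]
    return(out)
  }
  for (ch in seq_len(dims[3])) {
    plane <- out[, , ch]
    hp <- healthy_image[, , ch]
    plane[suppression_mask] <- hp[suppression_mask]
    out[, , ch] <- plane
  }
  out
}

#' Perceived grid distortion of a field under suppression
#'
#' Metamorphopsia is a geometric percept (deviation of straight lines), so
#' the metric is the mean residual displacement magnitude, in units of the
#' grid pitch, over Amsler grid-line pixels *not* covered by the
#' suppression mask.  It is exactly 0 for an empty field and whenever the
#' mask covers every distorted line pixel (displacements vanish identically
#' outside kernel supports).  An optional luminance term adds
#' `lum_weight * mean(1 - gain)` over the same pixels; the default weight 0
#' keeps the metric purely geometric.
#'
#' @param field A [distortion_field()].
#' @param suppression_mask Logical matrix or NULL.
#' @param rs A [raster_spec()].
#' @param gs A [grid_spec()].
#' @param lum_weight Weight of the luminance-loss add-on term.
#' @param line_mask Optional precomputed grid-line mask (skips re-rendering
#'   the grid).
#' @return Non-negative scalar metric.
#' @export
grid_distortion_metric <- function(field, suppression_mask, rs, gs,
                                   lum_weight = 0, line_mask = NULL) {
  stopifnot(inherits(field, "distortion_field"), inherits(rs, "raster_spec"),
            inherits(gs, "grid_spec"))
  if (is.null(line_mask)) line_mask <- render_amsler(gs, rs)$line_mask
  sel <- line_mask
  if (!is.null(suppression_mask)) sel <- sel & !suppression_mask
  pixel_metric(field, sel, rs, scale = 1 / gs$pitch_deg, lum_weight = lum_weight)
}

# Mean displacement magnitude (degrees * scale) + optional luminance term
# over the selected pixels.
pixel_metric <- function(field, sel, rs, scale = 1, lum_weight = 0) {
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0L || n_kernels(field) == 0L) return(0)
  pts <- px_to_deg(rs, cbind(idx[, 2] - 0.5, idx[, 1] - 0.5))
  d <- displacement_at(field, pts)
  m <- mean(sqrt(d[, 1]^2 + d[, 2]^2)) * scale
  if (lum_weight > 0)
    m <- m + lum_weight * mean(1 - luminance_gain_at(field, pts))
  m
}

#' Map a perception metric to the 0-5 categorical scale
#'
#' `round(5 * min(1, metric / ref_metric))` with half-up rounding: 0 is an
#' imperceptible distortion, 5 the strongest (the reference metric and
#' anything above it).  Monotone non-decreasing in the metric.
#'
#' @param metric Non-negative perception metric.
#' @param ref_metric Metric value mapped to score 5 (> 0).
#' @return Integer score in 0..5.
#' @export
to_score <- function(metric, ref_metric) {
  if (!is.numeric(ref_metric) || any(ref_metric <= 0))
    stopf("'ref_metric' must be > 0")
  as.integer(round_half_up(5 * pmin(1, metric / ref_metric)))
}

#' Legibility score of highlighted reading text under distortion
#'
#' The residual-displacement metric (mean displacement magnitude, degrees)
#' restricted to pixels of the highlighted word boxes not covered by the
#' suppression mask, mapped through [to_score()]: 0 is complete legibility,
#' 5 complete illegibility.
#'
#' @param field A [distortion_field()].
#' @param suppression_mask Logical matrix or NULL.
#' @param highlight_boxes n x 4 matrix of pixel rectangles (x0, y0, x1, y1)
#'   as returned by [render_reading_task()]; must lie within the raster.
#' @param rs A [raster_spec()].
#' @param ref_metric Metric mapped to score 5.
#' @return Integer score in 0..5.
#' @export
legibility_score <- function(field, suppression_mask, highlight_boxes, rs,
                             ref_metric) {
  to_score(reading_metric(field, suppression_mask, highlight_boxes, rs),
           ref_metric)
}

#' @rdname legibility_score
#' @export
reading_metric <- function(field, suppression_mask, highlight_boxes, rs) {
  stopifnot(inherits(field, "distortion_field"), inherits(rs, "raster_spec"))
  sel <- boxes_mask(highlight_boxes, rs)
  if (!is.null(suppression_mask)) sel <- sel & !suppression_mask
  pixel_metric(field, sel, rs, scale = 1)
}

boxes_mask <- function(boxes, rs) {
  m <- matrix(FALSE, rs$height_px, rs$width_px)
  if (is.null(boxes) || nrow(boxes) == 0L) return(m)
  if (any(boxes[, c(1, 3)] < 1 | boxes[, c(1, 3)] > rs$width_px) ||
      any(boxes[, c(2, 4)] < 1 | boxes[, c(2, 4)] > rs$height_px))
    stopf("highlight boxes must lie within the raster")
  for (i in seq_len(nrow(boxes)))
    m[boxes[i, 2]:boxes[i, 4], boxes[i, 1]:boxes[i, 3]] <- TRUE
  m
}

#' A noisy synthetic participant
#'
#' Stands in for a human subject: reports [to_score()] of the true
#' perception metric perturbed by seeded Gaussian noise on the score scale
#' and, with probability `lapse_rate`, replaced by a uniform random score.
#' With zero noise and zero lapse every response is a deterministic
#' function of the stimulus.  The participant carries its own RNG stream,
#' so response sequences are reproducible per seed and independent of the
#' caller's RNG.
#'
#' @param score_noise_sd Gaussian noise SD on the 0-5 score scale (>= 0).
#' @param lapse_rate Probability in \[0, 1) of a uniform random response.
#' @param seed Integer seed of the participant's private RNG stream.
#' @param hidden_field Optional [distortion_field()] the participant
#'   perceives (used by examiner-style calibration procedures).
#' @return An object of class `synthetic_participant`.
#' @export
synthetic_participant <- function(score_noise_sd = 0, lapse_rate = 0, seed = 1,
                                  hidden_field = NULL) {
  if (!is_number(score_noise_sd) || score_noise_sd < 0)
    stopf("'score_noise_sd' must be >= 0")
  if (!is_number(lapse_rate) || lapse_rate < 0 || lapse_rate >= 1)
    stopf("'lapse_rate' must lie in [0, 1)")
  if (!is.null(hidden_field)) stopifnot(inherits(hidden_field, "distortion_field"))
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  structure(list(score_noise_sd = score_noise_sd, lapse_rate = lapse_rate,
                 seed = as.integer(seed), hidden_field = hidden_field,
                 rng = env),
            class = "synthetic_participant")
}

# Run `expr` on the participant's private RNG stream, preserving the
# caller's global RNG state.
participant_rng <- function(participant, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(participant$rng$state)) set.seed(participant$seed)
  else assign(".Random.seed", participant$rng$state, envir = globalenv())
  out <- expr
  participant$rng$state <- get(".Random.seed", envir = globalenv())
  out
}

#' Score response of a synthetic participant
#'
#' @param participant A [synthetic_participant()].
#' @param metric True perception metric of the stimulus.
#' @param ref_metric Metric mapped to score 5.
#' @return Integer score in 0..5.
#' @export
participant_response <- function(participant, metric, ref_metric) {
  stopifnot(inherits(participant, "synthetic_participant"))
  base <- to_score(metric, ref_metric)
  if (participant$score_noise_sd == 0 && participant$lapse_rate == 0)
    return(base)
  participant_rng(participant, {
    if (participant$lapse_rate > 0 && stats::runif(1) < participant$lapse_rate) {
      sample(0:5, 1)
    } else {
      as.integer(clamp(round_half_up(
        base + stats::rnorm(1, 0, participant$score_noise_sd)), 0, 5))
    }
  })
}

# Continuous quantity reported with participant noise (relative Gaussian
# perturbation scaled by score_noise_sd); exact when noiseless.
participant_report <- function(participant, value, rel_sd = 0.02) {
  if (participant$score_noise_sd == 0) return(value)
  participant_rng(participant,
    value * exp(stats::rnorm(1, 0, rel_sd * participant$score_noise_sd)))
}

#' @export
print.synthetic_participant <- function(x, ...) {
  cat(sprintf("<synthetic_participant> seed %d, score noise sd %.3g, lapse %.3g%s\n",
              x$seed, x$score_noise_sd, x$lapse_rate,
              if (is.null(x$hidden_field)) ""
              else sprintf(", hidden field with %d kernel(s)",
                           n_kernels(x$hidden_field))))
  invisible(x)
}
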