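# Eye-movement quality control and AOI aggregation.
#
# Inputs are pre-detected fixation and saccade event tables (detection
# itself is out of scope). Trial-level criteria exclude whole trials on
# fixation measures; data-point criteria blank only the saccade measures of
# a retained trial; AOI-level criteria blank single AOI records. All
# criteria are evaluated as an (unordered) set of predicates, so flags do
# not depend on application order.

#' Default exclusion thresholds
#'
#' Trial exclusion: fewer than 4 or more than 40 fixations; total gaze
#' duration (sum of fixation durations) below 4571 ms or above 13714 ms
#' (the overall reading time); more than 5 fixations outside the valid
#' area; a negative outside-count, which is impossible for a well-formed
#' record, marks a corrupt trial. Saccade data points are blanked when a
#' trial has fewer than 3 saccades, its forward (progressive) saccades span
#' less than 13 cm in total, or the fixation and saccade counts differ by
#' more than 8. AOI records are blanked at more than 6 fixations or a gaze
#' duration above 4000 ms.
#'
#' @param ... Named overrides of individual thresholds.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(...) {
  th <- list(
    min_fixations = 4,
    max_fixations = 40,
    min_gaze_ms = 4571,
    max_gaze_ms = 13714,
    max_outside = 5,
    min_saccades = 3,
    min_forward_dist_cm = 13,
    max_fix_sacc_diff = 8,
    aoi_max_fixations = 6,
    aoi_max_gaze_ms = 4000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown) > 0) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  }
  th[names(dots)] <- dots
  th
}

# Trial-level criteria as named predicates over a per-trial summary row.
# Evaluated as a set: every violated criterion is recorded, so the flags
# are independent of evaluation order.
.trial_criteria <- function(th) {
  list(
    too_few_fixations = function(s) s$n_fixations < th$min_fixations,
    too_many_fixations = function(s) s$n_fixations > th$max_fixations,
    gaze_too_short = function(s) s$total_gaze_ms < th$min_gaze_ms,
    gaze_too_long = function(s) s$total_gaze_ms > th$max_gaze_ms,
    too_many_outside = function(s) s$n_outside > th$max_outside,
    corrupt_outside_count = function(s) s$n_outside < 0
  )
}

#' Summarise fixations per trial
#'
#' @param fixations Tibble with `trial_id`, `onset_ms`, `duration_ms`,
#'   `x_cm`, `y_cm` (origin at the stimulus image's top-left corner).
#' @param geometry A [screen_geometry()]; used for the valid-area test.
#' @param n_outside Optional externally recorded outside-valid-area counts
#'   (named by trial); when `NULL` they are computed from coordinates.
#' @return A tibble with one row per trial: `trial_id`, `n_fixations`,
#'   `total_gaze_ms`, `n_outside`.
#' @export
summarize_fixations <- function(fixations, geometry = screen_geometry(),
                                n_outside = NULL) {
  va <- valid_area_rect(geometry)
  ids <- unique(fixations$trial_id)
  rows <- lapply(ids, function(id) {
    f <- fixations[fixations$trial_id == id, , drop = FALSE]
    outside <- if (is.null(n_outside)) {
      sum(f$x_cm < va["x0"] | f$x_cm >= va["x1"] |
            f$y_cm < va["y0"] | f$y_cm >= va["y1"])
    } else {
      n_outside[[as.character(id)]]
    }
    tibble::tibble(
      trial_id = id,
      n_fixations = nrow(f),
      total_gaze_ms = sum(f$duration_ms),
      n_outside = outside
    )
  })
  do.call(rbind, rows)
}

#' Apply trial-level exclusion criteria
#'
#' Flags each trial with every violated criterion; a trial is excluded iff
#' at least one criterion fires. The valid-area test uses the geometry's
#' valid rectangle centred on the staff.
#'
#' @inheritParams summarize_fixations
#' @param thresholds A [qc_thresholds()] list.
#' @return The per-trial summary with `excluded` (logical) and
#'   `exclusion_reasons` (semicolon-separated criterion names, `""` when
#'   retained).
#' @export
apply_trial_exclusions <- function(fixations, geometry = screen_geometry(),
                                   thresholds = qc_thresholds(),
                                   n_outside = NULL) {
  summary <- summarize_fixations(fixations, geometry, n_outside)
  crit <- .trial_criteria(thresholds)
  reasons <- vapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, , drop = FALSE]
    fired <- names(crit)[vapply(crit, function(f) isTRUE(f(s)), logical(1))]
    paste(fired, collapse = ";")
  }, character(1))
  summary$excluded <- reasons != ""
  summary$exclusion_reasons <- reasons
  summary
}

#' Summarise saccades per trial
#'
#' @param saccades Tibble with `trial_id`, `onset_ms`, `amplitude_cm`,
#'   `direction` (`"progressive"` = rightward, `"regressive"` = leftward).
#' @return A tibble per trial: `n_saccades`, `n_progressive`,
#'   `n_regressive`, `dist_progressive_cm`, `dist_regressive_cm`,
#'   `mean_amp_progressive_cm`, `mean_amp_regressive_cm`.
#' @export
summarize_saccades <- function(saccades) {
  ids <- unique(saccades$trial_id)
  rows <- lapply(ids, function(id) {
    s <- saccades[saccades$trial_id == id, , drop = FALSE]
    prog <- s$direction == "progressive"
    tibble::tibble(
      trial_id = id,
      n_saccades = nrow(s),
      n_progressive = sum(prog),
      n_regressive = sum(!prog),
      dist_progressive_cm = sum(s$amplitude_cm[prog]),
      dist_regressive_cm = sum(s$amplitude_cm[!prog]),
      mean_amp_progressive_cm =
        if (any(prog)) mean(s$amplitude_cm[prog]) else NA_real_,
      mean_amp_regressive_cm =
        if (any(!prog)) mean(s$amplitude_cm[!prog]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Apply data-point exclusion criteria to saccade measures
#'
#' Where a criterion fires, only the saccade measure columns of that trial
#' become `NA`; the trial itself (and its fixation measures) is retained.
#'
#' @param trial_summary A join of [summarize_fixations()] and
#'   [summarize_saccades()] rows (must contain `n_fixations` and the
#'   saccade measure columns).
#' @param thresholds A [qc_thresholds()] list.
#' @return The summary with saccade measures blanked where violated and a
#'   `saccade_exclusion_reasons` column.
#' @export
apply_datapoint_exclusions <- function(trial_summary,
                                       thresholds = qc_thresholds()) {
  crit <- list(
    too_few_saccades = function(s) s$n_saccades < thresholds$min_saccades,
    forward_distance_too_small = function(s)
      s$dist_progressive_cm < thresholds$min_forward_dist_cm,
    fix_sacc_count_mismatch = function(s)
      abs(s$n_fixations - s$n_saccades) > thresholds$max_fix_sacc_diff
  )
  sacc_cols <- c("n_saccades", "n_progressive", "n_regressive",
                 "dist_progressive_cm", "dist_regressive_cm",
                 "mean_amp_progressive_cm", "mean_amp_regressive_cm")
  reasons <- vapply(seq_len(nrow(trial_summary)), function(i) {
    s <- trial_summary[i, , drop = FALSE]
    fired <- names(crit)[vapply(crit, function(f) isTRUE(f(s)), logical(1))]
    paste(fired, collapse = ";")
  }, character(1))
  blank <- reasons != ""
  for (col in intersect(sacc_cols, names(trial_summary))) {
    trial_summary[[col]][blank] <- NA
  }
  trial_summary$saccade_exclusion_reasons <- reasons
  trial_summary
}

#' Assign fixations to AOIs and compute pass measures
#'
#' Membership is point-in-rectangle with left/top boundaries inclusive and
#' right/bottom exclusive. Within a trial the fixation sequence (in
#' temporal order) decomposes, per AOI, into visit runs of consecutive
#' in-AOI fixations: the first run is the first pass, the run at the next
#' re-entry the second pass. Gaze durations are sums of member fixation
#' durations. An AOI never fixated carries no information and is marked
#' `missing`.
#'
#' @param fixations Tibble with `trial_id`, `onset_ms`, `duration_ms`,
#'   `x_cm`, `y_cm`.
#' @param aois AOI rectangles from [aoi_rects()] (overlap-checked there).
#' @return A tibble per trial x AOI: `n_fixations`, `n_first_pass`,
#'   `n_second_pass`, `n_later_pass`, `gaze_duration_ms`,
#'   `first_pass_duration_ms`, `second_pass_duration_ms`, `missing`.
#' @export
assign_fixations_to_aois <- function(fixations, aois = aoi_rects()) {
  .check_aoi_overlap(aois)
  ids <- unique(fixations$trial_id)
  rows <- list()
  for (id in ids) {
    f <- fixations[fixations$trial_id == id, , drop = FALSE]
    f <- f[order(f$onset_ms), , drop = FALSE]
    for (a in seq_len(nrow(aois))) {
      inside <- f$x_cm >= aois$x0[a] & f$x_cm < aois$x1[a] &
        f$y_cm >= aois$y0[a] & f$y_cm < aois$y1[a]
      runs <- rle(inside)
      visit <- integer(length(inside))
      v <- 0L
      pos <- 1L
      for (r in seq_along(runs$lengths)) {
        len <- runs$lengths[r]
        if (runs$values[r]) {
          v <- v + 1L
          visit[pos:(pos + len - 1L)] <- v
        }
        pos <- pos + len
      }
      n_in <- sum(inside)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial_id = id,
        aoi_index = aois$aoi_index[a],
        n_fixations = n_in,
        n_first_pass = sum(visit == 1L),
        n_second_pass = sum(visit == 2L),
        n_later_pass = sum(visit > 2L),
        gaze_duration_ms = sum(f$duration_ms[inside]),
        first_pass_duration_ms = sum(f$duration_ms[visit == 1L]),
        second_pass_duration_ms = sum(f$duration_ms[visit == 2L]),
        missing = n_in == 0L
      )
    }
  }
  do.call(rbind, rows)
}

#' Apply AOI-level exclusion criteria
#'
#' AOI records with more than `aoi_max_fixations` fixations or a gaze
#' duration above `aoi_max_gaze_ms` are treated as noise: their measures
#' are blanked and the record is marked `missing`.
#'
#' @param aoi_metrics Output of [assign_fixations_to_aois()].
#' @param thresholds A [qc_thresholds()] list.
#' @return The metrics with noisy records blanked and an
#'   `aoi_exclusion_reasons` column.
#' @export
apply_aoi_exclusions <- function(aoi_metrics,
                                 thresholds = qc_thresholds()) {
  crit <- list(
    too_many_fixations = function(s)
      s$n_fixations > thresholds$aoi_max_fixations,
    gaze_too_long = function(s)
      s$gaze_duration_ms > thresholds$aoi_max_gaze_ms
  )
  measure_cols <- c("n_fixations", "n_first_pass", "n_second_pass",
                    "n_later_pass", "gaze_duration_ms",
                    "first_pass_duration_ms", "second_pass_duration_ms")
  reasons <- vapply(seq_len(nrow(aoi_metrics)), function(i) {
    s <- aoi_metrics[i, , drop = FALSE]
    fired <- names(crit)[vapply(crit, function(f) isTRUE(f(s)), logical(1))]
    paste(fired, collapse = ";")
  }, character(1))
  blank <- reasons != ""
  for (col in measure_cols) aoi_metrics[[col]][blank] <- NA
  aoi_metrics$missing[blank] <- TRUE
  aoi_metrics$aoi_exclusion_reasons <- reasons
  aoi_metrics
}
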