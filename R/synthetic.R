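# Synthetic performers and gaze scans with known ground truth.
#
# The simulator emulates the error structure the scoring measures and the
# rhythm-error taxonomy assume: Gaussian onset jitter around the true grid
# position (truncated so onsets stay non-negative), an optional systematic
# delay, uniform pitch substitutions that never hit the true pitch, skipped
# stimulus notes, and extra notes inserted between stimulus onsets. Gaze
# scans move left to right across the staff with occasional regressions.

#' Performer error parameters
#'
#' @param onset_jitter_sd_ms SD of Gaussian onset jitter (>= 0).
#' @param systematic_delay_ms Constant onset shift (may be negative).
#' @param p_pitch_error Probability a played note's pitch is substituted.
#' @param p_skip Probability a stimulus note is not played.
#' @param p_add Probability an extra note is inserted in an inter-onset gap.
#' @param pitch_error_range_semitones Substitutions are drawn uniformly
#'   from +/- 1..range semitones (never 0).
#' @param seed Optional integer seed for a self-contained stream.
#' @return A named list of class `performer_params`.
#' @export
performer_params <- function(onset_jitter_sd_ms = 0,
                             systematic_delay_ms = 0,
                             p_pitch_error = 0,
                             p_skip = 0,
                             p_add = 0,
                             pitch_error_range_semitones = 2,
                             seed = NULL) {
  probs <- c(p_pitch_error, p_skip, p_add)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (onset_jitter_sd_ms < 0) stop("onset_jitter_sd_ms must be >= 0")
  if (pitch_error_range_semitones < 1) {
    stop("pitch_error_range_semitones must be >= 1")
  }
  structure(
    list(
      onset_jitter_sd_ms = onset_jitter_sd_ms,
      systematic_delay_ms = systematic_delay_ms,
      p_pitch_error = p_pitch_error,
      p_skip = p_skip,
      p_add = p_add,
      pitch_error_range_semitones = as.integer(pitch_error_range_semitones),
      seed = seed
    ),
    class = "performer_params"
  )
}

#' Simulate a performance of a stimulus melody
#'
#' Each stimulus note is skipped with `p_skip`; otherwise it is emitted at
#' its true onset plus the systematic delay plus truncated-Gaussian jitter,
#' with its pitch substituted with probability `p_pitch_error` (uniform
#' within the configured semitone range, never a zero offset). After each
#' played/skipped stimulus note, an extra note is inserted into the
#' following inter-onset gap with probability `p_add`; its pitch is drawn
#' from the melody's pitch range (mimicking adjacent-key errors).
#'
#' @param melody A `stimulus_melody`.
#' @param config A [timing_config()].
#' @param params A [performer_params()].
#' @param trial_id Identifier for the resulting record.
#' @return A list: `record` (a `performance_record`, already anchored to
#'   performance time) and `truth` (tibble of ground-truth events with
#'   `kind` in `played`/`skipped`/`added`, `stim_index`, `pitch_substituted`).
#' @export
simulate_performance <- function(melody, config = timing_config(),
                                 params = performer_params(),
                                 trial_id = "sim") {
  if (!is.null(params$seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(params$seed)
  }
  stim_ms <- melody_notes_ms(melody, config)
  n <- nrow(stim_ms)
  onset <- numeric(0); pitch <- integer(0); dur <- numeric(0)
  truth <- list()
  range_midis <- if (!is.null(melody$pitch_range)) {
    pitch_name_to_midi(melody$pitch_range)
  } else {
    unique(stim_ms$pitch)
  }
  gap_ends <- c(stim_ms$onset_ms[-1],
                if (n > 0) stim_ms$onset_ms[n] + stim_ms$duration_ms[n])
  for (i in seq_len(n)) {
    if (stats::runif(1) < params$p_skip) {
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "skipped", stim_index = i, onset_ms = stim_ms$onset_ms[i],
        pitch = stim_ms$pitch[i], pitch_substituted = FALSE)
    } else {
      o <- stim_ms$onset_ms[i] + params$systematic_delay_ms +
        .rtruncnorm_lower(1, 0, params$onset_jitter_sd_ms,
                          lower = -(stim_ms$onset_ms[i] +
                                      params$systematic_delay_ms))
      sub <- stats::runif(1) < params$p_pitch_error
      p <- stim_ms$pitch[i]
      if (sub) {
        r <- params$pitch_error_range_semitones
        offs <- c(-r:-1, 1:r)
        p <- p + sample(offs, 1L)
      }
      onset <- c(onset, o); pitch <- c(pitch, as.integer(p))
      dur <- c(dur, stim_ms$duration_ms[i] * 0.9)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "played", stim_index = i, onset_ms = o,
        pitch = as.integer(p), pitch_substituted = sub)
    }
    if (stats::runif(1) < params$p_add && gap_ends[i] > stim_ms$onset_ms[i]) {
      o <- stats::runif(1, stim_ms$onset_ms[i], gap_ends[i])
      p <- sample(range_midis, 1L)
      onset <- c(onset, o); pitch <- c(pitch, as.integer(p))
      dur <- c(dur, grid_step_ms(config))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "added", stim_index = NA_integer_, onset_ms = o,
        pitch = as.integer(p), pitch_substituted = FALSE)
    }
  }
  notes <- tibble::tibble(onset_ms = onset, pitch = pitch,
                          duration_ms = dur, velocity = 64L)
  record <- performance_record(notes, config = config, anchor = "file_start",
                               trial_id = trial_id,
                               melody_id = melody$melody_id)
  list(record = record, truth = do.call(rbind, truth))
}

# Gaussian truncated from below at `lower` (jitter must not push an onset
# below zero); falls back to the bound when sd is 0.
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower) break
    }
    out[i] <- x
  }
  out
}

#' Gaze scan parameters
#'
#' Defaults produce reading-scale trials: about four fixations per bar
#' (sixteen per melody), 600 ms mean fixation duration so the total gaze
#' duration of a typical trial falls inside the default retention window,
#' a 20% regression rate, and 0.3 cm coordinate noise.
#'
#' @param fixations_per_bar Mean fixations per bar (Poisson, floor 1).
#' @param fixation_duration_mean_ms,fixation_duration_sd_ms Fixation
#'   duration distribution (Gaussian truncated at 20 ms).
#' @param p_regression Probability a step moves leftward.
#' @param noise_sd_cm SD of isotropic Gaussian coordinate noise.
#' @param seed Optional integer seed.
#' @return A named list of class `gaze_params`.
#' @export
gaze_params <- function(fixations_per_bar = 4,
                        fixation_duration_mean_ms = 600,
                        fixation_duration_sd_ms = 150,
                        p_regression = 0.2,
                        noise_sd_cm = 0.3,
                        seed = NULL) {
  if (fixations_per_bar <= 0 || fixation_duration_mean_ms <= 0) {
    stop("means must be positive")
  }
  if (p_regression < 0 || p_regression > 1) {
    stop("p_regression must lie in [0, 1]")
  }
  structure(
    list(
      fixations_per_bar = fixations_per_bar,
      fixation_duration_mean_ms = fixation_duration_mean_ms,
      fixation_duration_sd_ms = fixation_duration_sd_ms,
      p_regression = p_regression,
      noise_sd_cm = noise_sd_cm,
      seed = seed
    ),
    class = "gaze_params"
  )
}

#' Simulate a gaze scan over the staff
#'
#' Fixation targets progress left to right across the staff width; with
#' probability `p_regression` a step instead jumps back toward an earlier
#' position. Coordinates get isotropic Gaussian noise, so large noise can
#' push fixations outside the valid area (exercising the exclusion rules).
#' Saccade events are derived from consecutive fixation displacements
#' (rightward = progressive).
#'
#' @param geometry A [screen_geometry()].
#' @param params A [gaze_params()].
#' @param n_bars Number of bars scanned.
#' @param trial_id,melody_id Identifiers for the emitted tables.
#' @return A list of tibbles: `fixations` (`trial_id`, `onset_ms`,
#'   `duration_ms`, `x_cm`, `y_cm`) and `saccades` (`trial_id`, `onset_ms`,
#'   `amplitude_cm`, `direction`).
#' @export
simulate_gaze <- function(geometry = screen_geometry(),
                          params = gaze_params(), n_bars = 4,
                          trial_id = "sim", melody_id = NA_character_) {
  if (!is.null(params$seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(params$seed)
  }
  n_fix <- max(2L, stats::rpois(1, params$fixations_per_bar * n_bars))
  staff_x0 <- (geometry$image_width_cm - geometry$staff_width_cm) / 2
  staff_x1 <- staff_x0 + geometry$staff_width_cm
  cy <- geometry$image_height_cm / 2
  # ideal scan: evenly spaced targets across the staff
  targets <- seq(staff_x0 + 0.5, staff_x1 - 0.5, length.out = n_fix)
  x <- numeric(n_fix)
  pos <- 1L
  x[1] <- targets[1]
  for (i in seq_len(n_fix)[-1]) {
    if (stats::runif(1) < params$p_regression && pos > 1L) {
      pos <- sample.int(pos - 1L, 1L)  # regress to an earlier target
    } else {
      pos <- min(pos + 1L, n_fix)
    }
    x[i] <- targets[pos]
  }
  if (params$noise_sd_cm > 0) {
    x <- x + stats::rnorm(n_fix, 0, params$noise_sd_cm)
    y <- cy + stats::rnorm(n_fix, 0, params$noise_sd_cm)
  } else {
    y <- rep(cy, n_fix)
  }
  durations <- pmax(20, stats::rnorm(n_fix, params$fixation_duration_mean_ms,
                                     params$fixation_duration_sd_ms))
  onsets <- cumsum(c(0, durations[-n_fix] + 30))  # 30 ms saccade gaps
  fixations <- tibble::tibble(
    trial_id = trial_id, melody_id = melody_id,
    onset_ms = onsets, duration_ms = durations, x_cm = x, y_cm = y
  )
  dx <- diff(x)
  saccades <- tibble::tibble(
    trial_id = trial_id, melody_id = melody_id,
    onset_ms = onsets[-1] - 15,
    amplitude_cm = abs(dx),
    direction = ifelse(dx >= 0, "progressive", "regressive")
  )
  list(fixations = fixations, saccades = saccades)
}

#' Parameter-recovery experiment
#'
#' For each row of a performer-parameter grid, simulates `n_reps`
#' performances of battery melodies, scores them and classifies their
#' errors, and tabulates estimated accuracy and taxonomy counts against the
#' generator's ground truth.
#'
#' @param grid A data frame whose columns name [performer_params()] fields
#'   (missing fields take their defaults).
#' @param melodies A list of `stimulus_melody` objects to perform (cycled
#'   over repetitions); defaults to one generated melody.
#' @param config A [timing_config()].
#' @param n_reps Simulated performances per grid row.
#' @param seed Integer seed for the whole experiment.
#' @return A tibble with one row per grid cell: the true parameters,
#'   `n_notes`, `onset_accuracy`, `pitch_accuracy`, `true_skip_fraction`,
#'   `est_skip_fraction` (taxonomy skips / stimulus notes),
#'   `true_add_fraction`, `est_add_fraction`.
#' @export
recovery_experiment <- function(grid, melodies = NULL,
                                config = timing_config(),
                                n_reps = 20, seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  if (is.null(melodies)) {
    melodies <- list(generate_melody(enumerate_pitch_ranges()[[1]],
                                     seed = seed))
  }
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    par_args <- as.list(grid[g, , drop = FALSE])
    params <- do.call(performer_params, par_args)
    n_notes <- 0; n_on <- 0; n_perf <- 0; n_pi <- 0
    n_true_skip <- 0; n_est_skip <- 0
    n_true_add <- 0; n_est_add <- 0
    for (r in seq_len(n_reps)) {
      mel <- melodies[[(r - 1L) %% length(melodies) + 1L]]
      sim <- simulate_performance(mel, config, params,
                                  trial_id = sprintf("g%d_r%d", g, r))
      sc <- score_performance(sim$record, mel, config)
      cls <- classify_errors(sc, config)
      n_notes <- n_notes + nrow(mel$notes)
      n_perf <- n_perf + sc$melody$n_performed
      n_on <- n_on + sc$melody$n_onset_correct
      n_pi <- n_pi + sc$melody$n_pitch_correct
      n_true_skip <- n_true_skip + sum(sim$truth$kind == "skipped")
      n_est_skip <- n_est_skip + cls$summary$n_skipped
      n_true_add <- n_true_add + sum(sim$truth$kind == "added")
      n_est_add <- n_est_add + cls$summary$n_added
    }
    rows[[g]] <- tibble::tibble(
      onset_jitter_sd_ms = params$onset_jitter_sd_ms,
      systematic_delay_ms = params$systematic_delay_ms,
      p_pitch_error = params$p_pitch_error,
      p_skip = params$p_skip,
      p_add = params$p_add,
      n_notes = n_notes,
      onset_accuracy = if (n_perf > 0) n_on / n_perf else NA_real_,
      pitch_accuracy = if (n_on > 0) n_pi / n_on else NA_real_,
      true_skip_fraction = n_true_skip / n_notes,
      est_skip_fraction = n_est_skip / n_notes,
      true_add_fraction = n_true_add / n_notes,
      est_add_fraction = n_est_add / n_notes
    )
  }
  do.call(rbind, rows)
}
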