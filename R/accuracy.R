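# Performance scoring: quantize performed onsets to the metric grid, match
# them against the stimulus, score pitch for correct-onset notes, and
# aggregate per melody and per note pair.
#
# The scoring frame places time zero at the first beat of bar 1, so the
# k-th grid position lies at k * 60000 / (tempo * grid_division) ms
# (at 70 bpm with a sixteenth grid, grid index 4 is 857.14... ms; a note
# played at 840 ms quantizes there).

#' Quantize onsets to the metric grid
#'
#' Each onset is moved to the closest grid position. Exact midpoints round
#' up (toward the later grid index). Onsets earlier than half a grid step
#' before zero are clamped to grid 0 with a warning.
#'
#' @param onset_ms Numeric vector of performed onsets in ms (time zero =
#'   first beat of the performance).
#' @param config A [timing_config()].
#' @param max_index Optional upper bound on the grid index (e.g. the last
#'   stimulus position plus one bar); `Inf` leaves indices unbounded.
#' @return A tibble with `grid_index` and `quantized_onset_ms` (full
#'   precision; round only for display).
#' @export
#' @examples
#' quantize_onset(840)  # grid 4, 857.14 ms
quantize_onset <- function(onset_ms, config = timing_config(),
                           max_index = Inf) {
  step <- grid_step_ms(config)
  early <- onset_ms < -step / 2
  if (any(early)) {
    warning(sprintf(
      "%d onset(s) more than half a grid step before zero; clamped to grid 0",
      sum(early)))
  }
  idx <- floor(onset_ms / step + 0.5)   # half-up tie rule
  idx[early] <- 0
  idx <- pmin(idx, max_index)
  tibble::tibble(
    grid_index = as.integer(idx),
    quantized_onset_ms = idx * step
  )
}

#' Stimulus notes as grid positions
#'
#' @param melody A `stimulus_melody`.
#' @param config A [timing_config()].
#' @return A tibble with `stim_index`, `grid_index`, `pitch` (midi),
#'   `onset_beats`. Errors if any stimulus onset is off-grid.
#' @export
stimulus_grid <- function(melody, config = timing_config()) {
  pos <- melody$notes$onset_beats * config$grid_division
  if (any(abs(pos - round(pos)) > 1e-9)) {
    stop("stimulus onsets do not lie on the quantization grid")
  }
  tibble::tibble(
    stim_index = seq_len(nrow(melody$notes)),
    grid_index = as.integer(round(pos)),
    pitch = as.integer(melody$notes$midi),
    onset_beats = melody$notes$onset_beats
  )
}

#' Score a performance against a stimulus melody
#'
#' Runs the three scoring steps in sequence: (1) quantize each performed
#' onset to the grid; (2) mark a performed note onset-correct iff its grid
#' index equals a stimulus note's grid index not already claimed by an
#' earlier performed note; (3) for onset-correct notes only, compare the
#' performed MIDI number with the stimulus pitch at that position
#' (incorrect-onset notes have no clear reference pitch, so their
#' `pitch_correct` is `NA`). Accuracy fractions are computed with
#' [melody_accuracy()] and, when the melody carries AOI/pair coding, per
#' note pair with [pair_accuracy()].
#'
#' @param performance A `performance_record`, or a note table with
#'   `onset_ms` and `pitch` columns.
#' @param melody A `stimulus_melody`.
#' @param config A [timing_config()].
#' @return A list of class `melody_score`: `notes` (per-note table),
#'   `melody` (one-row accuracy table), `pairs` (per-AOI table or `NULL`),
#'   `stimulus` (grid table with `matched` flags).
#' @export
#' @examples
#' stim <- melody_from_notes(data.frame(
#'   onset_beats = 0:3, duration_beats = 1,
#'   pitch = c("C4", "E4", "G4", "C5")))
#' perf <- data.frame(onset_ms = c(10, 880, 1300, 2400),
#'                    pitch = pitch_name_to_midi(c("C4", "F4", "G4", "C5")))
#' score_performance(perf, stim)$melody
score_performance <- function(performance, melody,
                              config = timing_config()) {
  notes <- if (inherits(performance, "performance_record")) {
    performance$notes
  } else {
    tibble::as_tibble(performance)
  }
  trial_id <- if (inherits(performance, "performance_record")) {
    performance$trial_id
  } else "trial"

  stim <- stimulus_grid(melody, config)
  max_idx <- if (nrow(stim) > 0) {
    max(stim$grid_index) + config$beats_per_bar * config$grid_division
  } else Inf

  if (nrow(notes) == 0) {
    note_scores <- tibble::tibble(
      trial_id = character(0), melody_id = character(0),
      note_index = integer(0), onset_ms = numeric(0), pitch = integer(0),
      grid_index = integer(0), quantized_onset_ms = numeric(0),
      onset_correct = logical(0), matched_stim = integer(0),
      pitch_correct = logical(0)
    )
  } else {
    ord <- order(notes$onset_ms)
    notes <- notes[ord, , drop = FALSE]
    q <- quantize_onset(notes$onset_ms, config, max_index = max_idx)
    matched_stim <- rep(NA_integer_, nrow(notes))
    claimed <- rep(FALSE, nrow(stim))
    for (i in seq_len(nrow(notes))) {
      hit <- which(stim$grid_index == q$grid_index[i] & !claimed)
      if (length(hit) > 0) {
        matched_stim[i] <- hit[1]
        claimed[hit[1]] <- TRUE
      }
    }
    onset_correct <- !is.na(matched_stim)
    pitch_correct <- rep(NA, nrow(notes))
    pitch_correct[onset_correct] <-
      notes$pitch[onset_correct] == stim$pitch[matched_stim[onset_correct]]
    note_scores <- tibble::tibble(
      trial_id = trial_id,
      melody_id = melody$melody_id,
      note_index = seq_len(nrow(notes)),
      onset_ms = notes$onset_ms,
      pitch = as.integer(notes$pitch),
      grid_index = q$grid_index,
      quantized_onset_ms = q$quantized_onset_ms,
      onset_correct = onset_correct,
      matched_stim = matched_stim,
      pitch_correct = as.logical(pitch_correct)
    )
  }

  stim$matched <- stim$stim_index %in% note_scores$matched_stim
  mel <- melody_accuracy(note_scores)
  mel$trial_id <- trial_id
  mel$melody_id <- melody$melody_id
  mel <- mel[, c("trial_id", "melody_id", setdiff(names(mel),
                                                  c("trial_id", "melody_id")))]
  pairs <- if (!is.null(melody$aoi_note_pairs)) {
    pair_accuracy(note_scores, melody, config)
  } else NULL

  structure(
    list(notes = note_scores, melody = mel, pairs = pairs, stimulus = stim),
    class = "melody_score"
  )
}

#' @export
print.melody_score <- function(x, ...) {
  cat("<melody_score>", x$melody$melody_id[1], "\n")
  cat(sprintf("  onset accuracy: %s   pitch accuracy: %s   (%d notes)\n",
              format(x$melody$onset_accuracy, digits = 3),
              format(x$melody$pitch_accuracy, digits = 3),
              x$melody$n_performed))
  invisible(x)
}

#' Per-melody accuracy fractions
#'
#' Onset accuracy is the fraction of performed notes with a correct onset;
#' pitch accuracy is, among correct-onset notes, the fraction with the
#' correct pitch. An empty denominator yields `NA` (never 0 or 1): a trial
#' with no correct onsets has no defined pitch accuracy.
#'
#' @param note_scores Note-level table from [score_performance()].
#' @return A one-row tibble: `n_performed`, `n_onset_correct`,
#'   `n_pitch_correct`, `onset_accuracy`, `pitch_accuracy`.
#' @export
melody_accuracy <- function(note_scores) {
  n <- nrow(note_scores)
  n_on <- sum(note_scores$onset_correct)
  n_pi <- sum(note_scores$pitch_correct, na.rm = TRUE)
  tibble::tibble(
    n_performed = n,
    n_onset_correct = n_on,
    n_pitch_correct = n_pi,
    onset_accuracy = if (n > 0) n_on / n else NA_real_,
    pitch_accuracy = if (n_on > 0) n_pi / n_on else NA_real_
  )
}

#' Per-note-pair (AOI) accuracy
#'
#' Restricts scoring to the two stimulus notes of each coded note pair
#' (the first two sounding notes of bars 2-4). Onset accuracy is the
#' fraction of the pair's two stimulus notes matched by a performed note;
#' pitch accuracy is computed over the matched ones, `NA` when neither was
#' performed at the correct position.
#'
#' @param note_scores Note-level table from [score_performance()].
#' @param melody A `stimulus_melody` with AOI/pair coding.
#' @param config A [timing_config()].
#' @return A tibble with one row per AOI: `aoi_index`, `pair_type`,
#'   `onset_accuracy`, `pitch_accuracy`.
#' @export
pair_accuracy <- function(note_scores, melody, config = timing_config()) {
  if (is.null(melody$aoi_note_pairs)) {
    warning("melody has no AOI/pair coding; nothing to score")
    return(tibble::tibble(aoi_index = integer(0), pair_type = character(0),
                          onset_accuracy = numeric(0),
                          pitch_accuracy = numeric(0)))
  }
  rows <- lapply(seq_along(melody$aoi_note_pairs), function(a) {
    bar <- a + 1L  # AOIs sit on bars 2..4
    in_bar <- which(melody$notes$bar == bar & melody$notes$is_pair_note)
    if (length(in_bar) != 2L) {
      warning("AOI ", a, " has no coded note pair; skipped")
      return(NULL)
    }
    matched_rows <- match(in_bar, note_scores$matched_stim)
    matched <- !is.na(matched_rows)
    pc <- note_scores$pitch_correct[matched_rows[matched]]
    tibble::tibble(
      aoi_index = a,
      pair_type = unname(melody$aoi_note_pairs[a]),
      onset_accuracy = mean(matched),
      pitch_accuracy = if (any(matched)) mean(pc) else NA_real_
    )
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
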