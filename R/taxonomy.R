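# Rhythm-error taxonomy: added, skipped, early and late notes, with
# continuous onset (beats) and pitch (semitones) deviations for early/late
# pairs.
#
# After onset matching, the unmatched stimulus notes and unmatched performed
# notes are paired by grid distance. The pairing is an exact non-crossing
# assignment: among assignments that pair as many notes as possible within
# the pairing radius, it minimises the total |grid deviation| (ties resolve
# toward pairing earlier notes). Performed partners earlier than their
# stimulus note are "early", later ones "late"; leftover performed notes are
# "added" and leftover stimulus notes "skipped". The strict reading of
# "skipped" (both neighbours performed with correct onsets) is reported
# alongside as `skipped_strict`.

#' Classify rhythm errors for one scored trial
#'
#' @param score A `melody_score` from [score_performance()].
#' @param config The [timing_config()] used for scoring.
#' @param radius_beats Pairing radius: an unmatched performed note farther
#'   than this from every unmatched stimulus note is "added" (and the
#'   stimulus note "skipped") regardless of proximity order. Default 1 beat.
#' @return A list of class `error_classification`: `table` (long tibble,
#'   one row per performed and per stimulus note, with `role`, `label`,
#'   `onset_deviation_beats`, `pitch_deviation_semitones`, `paired_note`,
#'   `skipped_strict`) and `summary` (see [error_summary()]).
#' @export
#' @examples
#' stim <- melody_from_notes(data.frame(
#'   onset_beats = 0:3, duration_beats = 1,
#'   pitch = c("C4", "D4", "E4", "F4")))
#' perf <- data.frame(onset_ms = beats_to_ms(c(0, 1, 2.75)),
#'                    pitch = pitch_name_to_midi(c("C4", "D4", "F4")))
#' cls <- classify_errors(score_performance(perf, stim))
#' subset(cls$table, label %in% c("early", "late"))
classify_errors <- function(score, config = timing_config(),
                            radius_beats = 1) {
  notes <- score$notes
  stim <- score$stimulus
  radius_steps <- radius_beats * config$grid_division

  perf_label <- ifelse(notes$onset_correct, "correct", "added")
  perf_dev_beats <- rep(NA_real_, nrow(notes))
  perf_dev_semi <- rep(NA_integer_, nrow(notes))
  perf_pair <- notes$matched_stim  # stimulus partner (correct or early/late)

  stim_status <- ifelse(stim$matched, "matched", "skipped")
  stim_pair <- rep(NA_integer_, nrow(stim))
  stim_pair[stim$matched] <- match(stim$stim_index, notes$matched_stim)[stim$matched]

  un_stim <- which(!stim$matched)
  un_perf <- which(!notes$onset_correct)
  if (length(un_stim) > 0 && length(un_perf) > 0) {
    pairs <- .assign_pairs(stim$grid_index[un_stim],
                           notes$grid_index[un_perf], radius_steps)
    for (k in seq_len(nrow(pairs))) {
      si <- un_stim[pairs$s[k]]
      pi <- un_perf[pairs$p[k]]
      dev_steps <- notes$grid_index[pi] - stim$grid_index[si]
      lab <- if (dev_steps < 0) "early" else "late"
      perf_label[pi] <- lab
      perf_dev_beats[pi] <- dev_steps / config$grid_division
      perf_dev_semi[pi] <- notes$pitch[pi] - stim$pitch[si]
      perf_pair[pi] <- si
      stim_status[si] <- lab
      stim_pair[si] <- pi
    }
  }

  # strict reading: skipped iff unperformed with both neighbours matched
  matched_flag <- stim$matched
  n_s <- nrow(stim)
  prev_ok <- c(TRUE, matched_flag[-n_s])
  next_ok <- c(matched_flag[-1], TRUE)
  skipped_strict <- !matched_flag & prev_ok & next_ok

  tbl <- rbind(
    tibble::tibble(
      trial_id = if (nrow(notes) > 0) notes$trial_id else character(0),
      melody_id = if (nrow(notes) > 0) notes$melody_id else character(0),
      role = rep("performed", nrow(notes)),
      note_index = notes$note_index,
      grid_index = notes$grid_index,
      pitch = notes$pitch,
      label = perf_label,
      onset_deviation_beats = perf_dev_beats,
      pitch_deviation_semitones = perf_dev_semi,
      paired_note = perf_pair,
      skipped_strict = rep(NA, nrow(notes))
    ),
    tibble::tibble(
      trial_id = rep(if (nrow(notes) > 0) notes$trial_id[1] else
        NA_character_, n_s),
      melody_id = rep(if (nrow(notes) > 0) notes$melody_id[1] else
        NA_character_, n_s),
      role = rep("stimulus", n_s),
      note_index = stim$stim_index,
      grid_index = stim$grid_index,
      pitch = stim$pitch,
      label = stim_status,
      onset_deviation_beats = rep(NA_real_, n_s),
      pitch_deviation_semitones = rep(NA_integer_, n_s),
      paired_note = stim_pair,
      skipped_strict = skipped_strict
    )
  )
  structure(list(table = tbl, summary = error_summary(tbl)),
            class = "error_classification")
}

# Exact pairing of unmatched stimulus grid positions s and unmatched
# performed grid positions p (both integer vectors): maximise the number of
# pairs with |s_i - p_j| <= radius, then minimise total |deviation|. For
# absolute distance on a line an optimal assignment can be taken
# non-crossing, so a dynamic program over the two sorted sequences is exact.
.assign_pairs <- function(s, p, radius) {
  os <- order(s); op <- order(p)
  ss <- s[os]; pp <- p[op]
  n <- length(ss); m <- length(pp)
  # value(i, j) for suffixes ss[i..n], pp[j..m]: (pairs, cost), lexicographic
  pairs_m <- matrix(0L, n + 1L, m + 1L)
  cost_m <- matrix(0, n + 1L, m + 1L)
  move <- matrix("", n + 1L, m + 1L)  # "pair", "skip_s", "skip_p"
  for (i in n:1) {
    for (j in m:1) {
      # candidates: (pairs, cost, move)
      best_pairs <- pairs_m[i + 1L, j]
      best_cost <- cost_m[i + 1L, j]
      best_move <- "skip_s"
      if (pairs_m[i, j + 1L] > best_pairs ||
          (pairs_m[i, j + 1L] == best_pairs &&
           cost_m[i, j + 1L] < best_cost)) {
        best_pairs <- pairs_m[i, j + 1L]
        best_cost <- cost_m[i, j + 1L]
        best_move <- "skip_p"
      }
      d <- abs(ss[i] - pp[j])
      if (d <= radius) {
        cand_pairs <- pairs_m[i + 1L, j + 1L] + 1L
        cand_cost <- cost_m[i + 1L, j + 1L] + d
        if (cand_pairs > best_pairs ||
            (cand_pairs == best_pairs && cand_cost <= best_cost)) {
          best_pairs <- cand_pairs
          best_cost <- cand_cost
          best_move <- "pair"
        }
      }
      pairs_m[i, j] <- best_pairs
      cost_m[i, j] <- best_cost
      move[i, j] <- best_move
    }
  }
  res_s <- integer(0); res_p <- integer(0)
  i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    mv <- move[i, j]
    if (mv == "pair") {
      res_s <- c(res_s, os[i]); res_p <- c(res_p, op[j])
      i <- i + 1L; j <- j + 1L
    } else if (mv == "skip_s") {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  data.frame(s = res_s, p = res_p)
}

#' Summarise an error classification
#'
#' @param classification An `error_classification` (or its `table`).
#' @return A one-row tibble: per-label counts over performed notes
#'   (`n_correct`, `n_added`, `n_early`, `n_late`), `n_skipped` over
#'   stimulus notes, `n_skipped_strict`, and mean absolute onset/pitch
#'   deviations over early/late pairs (`NA` when there are none).
#' @export
error_summary <- function(classification) {
  tbl <- if (inherits(classification, "error_classification")) {
    classification$table
  } else classification
  perf <- tbl[tbl$role == "performed", , drop = FALSE]
  stim <- tbl[tbl$role == "stimulus", , drop = FALSE]
  devs <- perf$onset_deviation_beats[perf$label %in% c("early", "late")]
  pdevs <- perf$pitch_deviation_semitones[perf$label %in% c("early", "late")]
  tibble::tibble(
    n_performed = nrow(perf),
    n_stimulus = nrow(stim),
    n_correct = sum(perf$label == "correct"),
    n_added = sum(perf$label == "added"),
    n_early = sum(perf$label == "early"),
    n_late = sum(perf$label == "late"),
    n_skipped = sum(stim$label == "skipped"),
    n_skipped_strict = sum(stim$skipped_strict, na.rm = TRUE),
    mean_abs_onset_deviation_beats =
      if (length(devs) > 0) mean(abs(devs)) else NA_real_,
    mean_abs_pitch_deviation_semitones =
      if (length(pdevs) > 0) mean(abs(pdevs)) else NA_real_
  )
}
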