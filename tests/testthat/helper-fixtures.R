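# Shared fixtures: small stimuli and performances built in code.

# Four quarter notes C4 E4 G4 C5 at beats 0..3 (the worked-example stimulus).
quarter_note_stimulus <- function(pitches = c("C4", "E4", "G4", "C5")) {
  melody_from_notes(data.frame(
    onset_beats = seq_along(pitches) - 1,
    duration_beats = 1,
    pitch = pitches
  ), melody_id = "four-quarters")
}

# A performance table from beat positions and pitch names, with optional
# per-note ms offsets.
performance_at_beats <- function(beats, pitches, offset_ms = 0,
                                 tempo_bpm = 70) {
  data.frame(
    onset_ms = beats * 60000 / tempo_bpm + offset_ms,
    pitch = pitch_name_to_midi(pitches),
    duration_ms = 200
  )
}

# A synthetic fixation table for one trial: n fixations of given durations
# at given x positions (cm), y on the staff centre line.
fixation_trial <- function(trial_id, x_cm, duration_ms = 500,
                           y_cm = screen_geometry()$image_height_cm / 2) {
  n <- length(x_cm)
  tibble::tibble(
    trial_id = trial_id,
    onset_ms = cumsum(c(0, rep(530, n - 1))),
    duration_ms = rep_len(duration_ms, n),
    x_cm = x_cm,
    y_cm = rep_len(y_cm, n)
  )
}

# Exhaustive oracle for the early/late pairing: enumerate every injective
# assignment of unmatched stimulus grids to unmatched performed grids within
# `radius`, maximise pair count then minimise total |deviation|. Returns the
# optimum and whether the optimal pair set is unique.
exhaustive_assignment <- function(s, p, radius) {
  best <- list(pairs = -1L, cost = Inf, sets = list())
  recurse <- function(i, avail, cur_pairs, cur_cost, cur_set) {
    if (i > length(s)) {
      if (cur_pairs > best$pairs ||
          (cur_pairs == best$pairs && cur_cost < best$cost - 1e-9)) {
        best <<- list(pairs = cur_pairs, cost = cur_cost, sets = list(cur_set))
      } else if (cur_pairs == best$pairs &&
                 abs(cur_cost - best$cost) <= 1e-9) {
        best$sets[[length(best$sets) + 1L]] <<- cur_set
      }
      return(invisible())
    }
    recurse(i + 1L, avail, cur_pairs, cur_cost, cur_set)  # leave s[i] unpaired
    for (j in which(avail)) {
      d <- abs(s[i] - p[j])
      if (d <= radius) {
        avail2 <- avail
        avail2[j] <- FALSE
        recurse(i + 1L, avail2, cur_pairs + 1L, cur_cost + d,
                rbind(cur_set, c(i, j)))
      }
    }
  }
  recurse(1L, rep(TRUE, length(p)), 0L, 0,
          matrix(integer(0), ncol = 2))
  sets <- lapply(best$sets, function(m) {
    if (nrow(m) == 0) return("")
    paste(apply(m[order(m[, 1]), , drop = FALSE], 1, paste, collapse = "-"),
          collapse = ";")
  })
  list(pairs = best$pairs, cost = best$cost,
       unique = length(unique(unlist(sets))) == 1L,
       set = sets[[1]])
}

# Canonical string form of the package pairing, for oracle comparison.
pairing_set_string <- function(cls_table, un_stim, un_perf) {
  perf <- cls_table[cls_table$role == "performed" &
                      cls_table$label %in% c("early", "late"), , drop = FALSE]
  if (nrow(perf) == 0) return("")
  si <- match(perf$paired_note, un_stim)
  pj <- match(perf$note_index, un_perf)
  ord <- order(si)
  paste(paste(si[ord], pj[ord], sep = "-"), collapse = ";")
}
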