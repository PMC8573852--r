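# Performance I/O: Standard MIDI Files (format 0/1), the tabular note-event
# dialect, and the result-table writers.
#
# The SMF layer is deliberately minimal: note on/off and set-tempo meta
# events are honoured, everything else is skipped. Ticks are converted to
# absolute milliseconds through the file's tempo map, so multi-tempo files
# read correctly; files written here carry a single tempo.

.DEFAULT_PPQ <- 480L

# ---- variable-length quantities ------------------------------------------

.varlen_encode <- function(value) {
  stopifnot(value >= 0)
  bytes <- as.integer(value %% 128L)
  value <- value %/% 128L
  while (value > 0) {
    bytes <- c(as.integer(value %% 128L) + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

.varlen_decode <- function(bytes, pos) {
  value <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    value <- value * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = value, pos = pos)
}

.uint <- function(bytes, pos, n) {
  sum(as.integer(bytes[pos:(pos + n - 1L)]) * 256^((n - 1L):0))
}

.uint_bytes <- function(value, n) {
  as.raw((value %/% 256^((n - 1L):0)) %% 256)
}

# ---- writing --------------------------------------------------------------

#' Write a note table to a Standard MIDI File
#'
#' Produces a single-track format-0 file with one set-tempo event. Onsets
#' and durations in milliseconds are converted to ticks at the given ppq.
#'
#' @param notes A data frame with columns `onset_ms`, `pitch`, `duration_ms`
#'   and optionally `velocity` (default 64).
#' @param path Output file path.
#' @param tempo_bpm Tempo written to the file.
#' @param ppq Ticks per quarter note.
#' @return `path`, invisibly.
#' @export
write_smf <- function(notes, path, tempo_bpm = 70, ppq = .DEFAULT_PPQ) {
  notes <- as.data.frame(notes)
  if (!"velocity" %in% names(notes)) notes$velocity <- 64L
  if (nrow(notes) > 0 &&
      (any(notes$pitch < 0) || any(notes$pitch > 127))) {
    stop("pitch outside MIDI range 0-127")
  }
  ms_per_tick <- 60000 / (tempo_bpm * ppq)
  ev <- data.frame(
    tick = integer(0), on = logical(0), pitch = integer(0), vel = integer(0)
  )
  if (nrow(notes) > 0) {
    on_ticks <- round(notes$onset_ms / ms_per_tick)
    off_ticks <- round((notes$onset_ms + notes$duration_ms) / ms_per_tick)
    ev <- data.frame(
      tick = c(on_ticks, off_ticks),
      on = rep(c(TRUE, FALSE), each = nrow(notes)),
      pitch = rep(as.integer(notes$pitch), 2L),
      vel = c(as.integer(notes$velocity), rep(0L, nrow(notes)))
    )
    # note-offs sort before note-ons at the same tick
    ev <- ev[order(ev$tick, ev$on), , drop = FALSE]
  }
  track <- raw(0)
  # tempo meta event at delta 0
  usq <- round(60e6 / tempo_bpm)
  track <- c(track, as.raw(c(0x00, 0xFF, 0x51, 0x03)), .uint_bytes(usq, 3L))
  last_tick <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last_tick
    last_tick <- ev$tick[i]
    status <- if (ev$on[i]) 0x90 else 0x80
    track <- c(track, .varlen_encode(delta),
               as.raw(c(status, ev$pitch[i], ev$vel[i])))
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))
  header <- c(charToRaw("MThd"), .uint_bytes(6L, 4L), .uint_bytes(0L, 2L),
              .uint_bytes(1L, 2L), .uint_bytes(ppq, 2L))
  body <- c(charToRaw("MTrk"), .uint_bytes(length(track), 4L), track)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

# ---- reading --------------------------------------------------------------

#' Read note events from a Standard MIDI File
#'
#' Parses all tracks, merges their tempo maps and converts ticks to
#' absolute milliseconds. Note-on events with velocity 0 are treated as
#' note-offs; a second note-on on a sounding key closes the earlier note at
#' the later onset with a warning; notes left open at end-of-track are
#' closed there with a warning.
#'
#' @param path Path to a format 0 or 1 SMF.
#' @return A tibble with `onset_ms`, `pitch`, `duration_ms`, `velocity`,
#'   sorted by onset.
#' @export
read_smf <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop("not a Standard MIDI File (missing MThd header): ", path)
  }
  division <- .uint(bytes, 13L, 2L)
  if (division >= 32768) stop("SMPTE time division is not supported: ", path)
  n_tracks <- .uint(bytes, 11L, 2L)
  pos <- 15L
  tempo_map <- data.frame(tick = 0, usq = 500000)  # default 120 bpm
  raw_notes <- list()
  for (trk in seq_len(n_tracks)) {
    if (pos + 7L > length(bytes) + 1L) {
      stop(sprintf("truncated file at byte %d: %s", pos, path))
    }
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop(sprintf("expected MTrk chunk at byte %d: %s", pos, path))
    }
    track_len <- .uint(bytes, pos + 4L, 4L)
    p <- pos + 8L
    track_end <- p + track_len
    tick <- 0
    status <- NULL
    open_notes <- list()  # key -> list(tick, vel)
    while (p < track_end) {
      d <- .varlen_decode(bytes, p)
      tick <- tick + d$value
      p <- d$pos
      b <- as.integer(bytes[p])
      if (b >= 128L) {
        status <- b
        p <- p + 1L
      } else if (is.null(status)) {
        stop(sprintf("running status without prior status byte at byte %d: %s",
                     p, path))
      }
      hi <- status %/% 16L
      if (status == 255L) {            # meta event
        type <- as.integer(bytes[p]); p <- p + 1L
        d <- .varlen_decode(bytes, p); p <- d$pos
        if (type == 0x51 && d$value == 3L) {
          tempo_map <- rbind(tempo_map,
                             data.frame(tick = tick, usq = .uint(bytes, p, 3L)))
        }
        p <- p + d$value
      } else if (status %in% c(240L, 247L)) {  # sysex
        d <- .varlen_decode(bytes, p); p <- d$pos + d$value
      } else if (hi %in% c(12L, 13L)) {  # program change / channel pressure
        p <- p + 1L
      } else if (hi %in% c(8L, 9L, 10L, 11L, 14L)) {
        key <- as.integer(bytes[p])
        val <- as.integer(bytes[p + 1L])
        p <- p + 2L
        if (hi == 9L && val > 0L) {      # note on
          k <- as.character(key)
          if (!is.null(open_notes[[k]])) {
            warning(sprintf(
              "overlapping note-on for pitch %d; closing earlier note at tick %d",
              key, tick))
            raw_notes[[length(raw_notes) + 1L]] <-
              c(open_notes[[k]]$tick, tick, key, open_notes[[k]]$vel)
          }
          open_notes[[k]] <- list(tick = tick, vel = val)
        } else if (hi == 8L || (hi == 9L && val == 0L)) {  # note off
          k <- as.character(key)
          if (!is.null(open_notes[[k]])) {
            raw_notes[[length(raw_notes) + 1L]] <-
              c(open_notes[[k]]$tick, tick, key, open_notes[[k]]$vel)
            open_notes[[k]] <- NULL
          }
        }
      } else {
        stop(sprintf("unsupported status byte 0x%X at byte %d: %s",
                     status, p, path))
      }
    }
    for (k in names(open_notes)) {
      warning(sprintf("note %s left open; closed at end of track", k))
      raw_notes[[length(raw_notes) + 1L]] <-
        c(open_notes[[k]]$tick, tick, as.integer(k), open_notes[[k]]$vel)
    }
    pos <- track_end
  }
  tempo_map <- tempo_map[order(tempo_map$tick), , drop = FALSE]
  tempo_map <- tempo_map[!duplicated(tempo_map$tick, fromLast = TRUE), ,
                         drop = FALSE]
  tick_to_ms <- .make_tick_to_ms(tempo_map, division)
  if (length(raw_notes) == 0) {
    return(tibble::tibble(onset_ms = numeric(0), pitch = integer(0),
                          duration_ms = numeric(0), velocity = integer(0)))
  }
  m <- do.call(rbind, raw_notes)
  out <- tibble::tibble(
    onset_ms = tick_to_ms(m[, 1]),
    pitch = as.integer(m[, 3]),
    duration_ms = tick_to_ms(m[, 2]) - tick_to_ms(m[, 1]),
    velocity = as.integer(m[, 4])
  )
  out[order(out$onset_ms, out$pitch), , drop = FALSE]
}

.make_tick_to_ms <- function(tempo_map, ppq) {
  # cumulative ms at each tempo-change tick
  n <- nrow(tempo_map)
  cum_ms <- numeric(n)
  for (i in seq_len(n)[-1]) {
    cum_ms[i] <- cum_ms[i - 1] +
      (tempo_map$tick[i] - tempo_map$tick[i - 1]) *
      tempo_map$usq[i - 1] / (1000 * ppq)
  }
  function(tick) {
    seg <- findInterval(tick, tempo_map$tick)
    seg[seg < 1L] <- 1L
    cum_ms[seg] + (tick - tempo_map$tick[seg]) *
      tempo_map$usq[seg] / (1000 * ppq)
  }
}

# ---- performance records ---------------------------------------------------

#' Read a recorded performance
#'
#' Accepts either a Standard MIDI File or a CSV note table (columns
#' `onset_ms`, `pitch_midi`, `duration_ms`, optional `velocity`). Onsets are
#' re-anchored so that time zero is the scoring frame's origin:
#' `"count_in_end"` (default) subtracts the count-in duration, so zero is
#' the first beat of the performance; `"file_start"` keeps file time;
#' `"first_note"` subtracts the first onset.
#'
#' @param path Input file.
#' @param config A [timing_config()] (used for the count-in duration).
#' @param anchor One of `"count_in_end"`, `"file_start"`, `"first_note"`.
#' @param trial_id,melody_id Identifiers stored with the record.
#' @return An object of class `performance_record`: list with `trial_id`,
#'   `melody_id`, `anchor` and `notes` (tibble sorted by onset).
#' @export
read_performance <- function(path, config = timing_config(),
                             anchor = c("count_in_end", "file_start",
                                        "first_note"),
                             trial_id = basename(path),
                             melody_id = NA_character_) {
  anchor <- match.arg(anchor)
  is_smf <- FALSE
  if (file.size(path) >= 4) {
    magic <- readBin(path, "raw", n = 4)
    is_smf <- identical(rawToChar(magic), "MThd")
  }
  notes <- if (is_smf) {
    read_smf(path)
  } else {
    .read_note_csv(path)
  }
  performance_record(notes, config = config, anchor = anchor,
                     trial_id = trial_id, melody_id = melody_id)
}

.read_note_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_ms", "pitch_midi", "duration_ms")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("note CSV ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  bad <- df$pitch_midi < 0 | df$pitch_midi > 127 | is.na(df$pitch_midi)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with pitch outside 0-127 in %s",
                    sum(bad), path))
    df <- df[!bad, , drop = FALSE]
  }
  tibble::tibble(
    onset_ms = as.numeric(df$onset_ms),
    pitch = as.integer(df$pitch_midi),
    duration_ms = as.numeric(df$duration_ms),
    velocity = if (is.null(df$velocity)) 64L else as.integer(df$velocity)
  )
}

#' Construct a performance record from a note table
#'
#' @param notes A data frame with `onset_ms`, `pitch`, `duration_ms` and
#'   optional `velocity` columns (file-time onsets).
#' @inheritParams read_performance
#' @return A `performance_record`.
#' @export
performance_record <- function(notes, config = timing_config(),
                               anchor = c("count_in_end", "file_start",
                                          "first_note"),
                               trial_id = "trial", melody_id = NA_character_) {
  anchor <- match.arg(anchor)
  notes <- tibble::as_tibble(notes)
  if (!"velocity" %in% names(notes)) notes$velocity <- 64L
  if (nrow(notes) > 0 && any(notes$duration_ms <= 0)) {
    stop("note durations must be positive")
  }
  offset <- switch(anchor,
    file_start = 0,
    count_in_end = beats_to_ms(config$count_in_bars * config$beats_per_bar,
                               config$tempo_bpm),
    first_note = if (nrow(notes) > 0) min(notes$onset_ms) else 0
  )
  notes$onset_ms <- notes$onset_ms - offset
  notes <- notes[order(notes$onset_ms, notes$pitch), , drop = FALSE]
  structure(
    list(trial_id = trial_id, melody_id = melody_id, anchor = anchor,
         notes = notes),
    class = "performance_record"
  )
}

#' @export
print.performance_record <- function(x, ...) {
  cat("<performance_record>", x$trial_id,
      sprintf("(%d notes, anchor = %s)\n", nrow(x$notes), x$anchor))
  invisible(x)
}

#' Write a performance note table to CSV
#'
#' Uses the documented dialect: `onset_ms`, `pitch_midi`, `duration_ms`,
#' `velocity`.
#'
#' @param x A `performance_record` or note table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(x, path) {
  notes <- if (inherits(x, "performance_record")) x$notes else
    tibble::as_tibble(x)
  out <- data.frame(
    onset_ms = notes$onset_ms,
    pitch_midi = notes$pitch,
    duration_ms = notes$duration_ms,
    velocity = if (!"velocity" %in% names(notes)) 64L else notes$velocity
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write scoring result tables
#'
#' Emits `notes.csv` (one row per performed note: quantized onset, grid
#' index, correctness flags, error label and deviations), `melodies.csv`
#' (per-melody accuracy fractions and counts) and `errors.csv` (the full
#' error-classification table including skipped stimulus notes). Empty
#' inputs produce header-only files.
#'
#' @param note_scores Note-level table from [score_performance()] (the
#'   `notes` element), possibly row-bound over trials.
#' @param melody_scores Melody-level table (the `melody` element).
#' @param errors Error table from [classify_errors()] (`$table`), or `NULL`.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(note_scores, melody_scores, errors = NULL,
                          dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    notes = file.path(dir, "notes.csv"),
    melodies = file.path(dir, "melodies.csv"),
    errors = file.path(dir, "errors.csv")
  )
  utils::write.csv(as.data.frame(note_scores), paths[["notes"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(melody_scores), paths[["melodies"]],
                   row.names = FALSE)
  if (is.null(errors)) {
    errors <- tibble::tibble(
      trial_id = character(0), melody_id = character(0),
      role = character(0), note_index = integer(0), grid_index = integer(0),
      pitch = integer(0), label = character(0),
      onset_deviation_beats = numeric(0),
      pitch_deviation_semitones = integer(0), paired_note = integer(0),
      skipped_strict = logical(0)
    )
  }
  utils::write.csv(as.data.frame(errors), paths[["errors"]],
                   row.names = FALSE)
  invisible(paths)
}
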