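# Stimulus melody generation: random phrase order plus a constrained
# diatonic pitch walk within a five-note range.

#' Generate one stimulus melody
#'
#' Concatenates the four one-bar rhythmic phrases in a random order (each
#' phrase type exactly once) and assigns pitches by a constrained walk: the
#' first pitch is drawn uniformly from the five-note range; every later
#' pitch is drawn uniformly from the range notes at most one scale position
#' from the previous pitch (repetition allowed), so the melody contains no
#' leaps larger than one scale step.
#'
#' @param pitch_range Character vector of 5 adjacent C-major pitch names
#'   (see [enumerate_pitch_ranges()]).
#' @param phrase_templates Named list of phrase templates, one per
#'   [pair_types()] value; defaults to [default_phrase_templates()].
#' @param phrase_order Optional explicit permutation of [pair_types()];
#'   randomized when `NULL`.
#' @param melody_id Identifier stored with the melody.
#' @param set_index Set number (0-3) stored with the melody.
#' @param seed Optional integer; when given, the RNG is seeded locally so
#'   the melody is reproducible without disturbing the caller's RNG stream.
#' @return An object of class `stimulus_melody`: a list with `melody_id`,
#'   `set_index`, `phrase_order`, `pitch_range`, `notes` (tibble with
#'   `onset_beats`, `duration_beats`, `pitch`, `midi`, `scale_index`, `bar`,
#'   `pair_type`, `is_pair_note`) and `aoi_note_pairs` (named character
#'   vector mapping AOI index to pair type for bars 2-4).
#' @export
#' @examples
#' m <- generate_melody(enumerate_pitch_ranges()[[1]], seed = 1)
#' m$phrase_order
generate_melody <- function(pitch_range,
                            phrase_templates = default_phrase_templates(),
                            phrase_order = NULL,
                            melody_id = "melody",
                            set_index = 0L,
                            seed = NULL) {
  if (length(pitch_range) != 5) stop("pitch_range must contain 5 notes")
  range_idx <- pitch_name_to_scale_index(pitch_range)
  if (!all(diff(sort(range_idx)) == 1L)) {
    stop("pitch_range must be 5 adjacent C-major scale notes")
  }
  if (!setequal(names(phrase_templates), pair_types())) {
    stop("phrase_templates must contain exactly the four pair types")
  }
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (is.null(phrase_order)) {
    phrase_order <- sample(pair_types())
  } else if (!setequal(phrase_order, pair_types()) ||
             length(phrase_order) != 4) {
    stop("phrase_order must be a permutation of the four pair types")
  }

  bars <- lapply(seq_along(phrase_order), function(b) {
    ph <- phrase_templates[[phrase_order[b]]]
    notes <- ph[!ph$is_rest, , drop = FALSE]
    tibble::tibble(
      onset_beats = notes$onset_beats + (b - 1) * 4,
      duration_beats = notes$duration_beats,
      bar = b,
      pair_type = phrase_order[b],
      is_pair_note = seq_len(nrow(notes)) <= 2L
    )
  })
  notes <- do.call(rbind, bars)

  # constrained walk over scale indices
  idx <- sort(range_idx)
  walk <- integer(nrow(notes))
  walk[1] <- sample(idx, 1L)
  for (i in seq_len(nrow(notes))[-1]) {
    nbrs <- idx[abs(idx - walk[i - 1]) <= 1L]
    walk[i] <- if (length(nbrs) == 1L) nbrs else sample(nbrs, 1L)
  }
  notes$pitch <- scale_index_to_pitch_name(walk)
  notes$midi <- scale_index_to_midi(walk)
  notes$scale_index <- walk
  notes <- notes[, c("onset_beats", "duration_beats", "pitch", "midi",
                     "scale_index", "bar", "pair_type", "is_pair_note")]

  aoi_bars <- 2:4
  aoi_note_pairs <- phrase_order[aoi_bars]
  names(aoi_note_pairs) <- as.character(seq_along(aoi_bars))

  structure(
    list(
      melody_id = melody_id,
      set_index = as.integer(set_index),
      phrase_order = phrase_order,
      pitch_range = sort(pitch_range)[order(sort(range_idx))],
      notes = notes,
      aoi_note_pairs = aoi_note_pairs
    ),
    class = "stimulus_melody"
  )
}

#' @export
print.stimulus_melody <- function(x, ...) {
  cat("<stimulus_melody>", x$melody_id,
      sprintf("(set %d)\n", x$set_index))
  cat("  phrases:", paste(x$phrase_order, collapse = " | "), "\n")
  cat("  range:  ", paste(x$pitch_range, collapse = " "), "\n")
  cat("  notes:  ", nrow(x$notes), "over",
      max(x$notes$onset_beats + x$notes$duration_beats), "beats\n")
  invisible(x)
}

#' Build a stimulus melody from a plain note table
#'
#' Wraps an arbitrary note list (in beats) as a `stimulus_melody` so that
#' externally defined stimuli can be scored with the same pipeline as
#' generated ones. No phrase or pitch-walk invariants are imposed.
#'
#' @param notes A data frame with columns `onset_beats`, `duration_beats`
#'   and either `midi` or `pitch` (scientific names).
#' @param melody_id Identifier for the melody.
#' @return A `stimulus_melody` without AOI/pair annotations.
#' @export
melody_from_notes <- function(notes, melody_id = "external") {
  notes <- tibble::as_tibble(notes)
  if (!"midi" %in% names(notes)) {
    if (!"pitch" %in% names(notes)) {
      stop("notes need a 'midi' or 'pitch' column")
    }
    notes$midi <- pitch_name_to_midi(notes$pitch)
  }
  if (!"pitch" %in% names(notes)) notes$pitch <- NA_character_
  if (!all(c("onset_beats", "duration_beats") %in% names(notes))) {
    stop("notes need 'onset_beats' and 'duration_beats' columns")
  }
  notes <- notes[order(notes$onset_beats), , drop = FALSE]
  structure(
    list(
      melody_id = melody_id,
      set_index = NA_integer_,
      phrase_order = NULL,
      pitch_range = NULL,
      notes = notes,
      aoi_note_pairs = NULL
    ),
    class = "stimulus_melody"
  )
}

#' Generate the full stimulus battery
#'
#' Builds four sets of twelve melodies (48 in total). One pitch range is
#' drawn per set from the nine candidate ranges; melody seeds are split
#' deterministically from `master_seed` (per-set, per-melody streams) so a
#' battery is exactly reproducible.
#'
#' @param config A [timing_config()] (kept with the battery for rendering).
#' @param master_seed Integer master seed.
#' @param n_sets,melodies_per_set Battery dimensions (defaults 4 and 12).
#' @param phrase_templates Phrase templates passed to [generate_melody()].
#' @return An object of class `stimulus_battery`: list with `melodies`
#'   (list of 48 `stimulus_melody`), `manifest` (tibble; see
#'   [battery_manifest()]), `config`, `master_seed`.
#' @export
#' @examples
#' b <- generate_battery(master_seed = 1)
#' nrow(b$manifest)  # 48
generate_battery <- function(config = timing_config(), master_seed = 1,
                             n_sets = 4, melodies_per_set = 12,
                             phrase_templates = default_phrase_templates()) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(master_seed)
  ranges <- enumerate_pitch_ranges("C4", "D5")
  range_pick <- sample.int(length(ranges), n_sets, replace = TRUE)
  # one sub-seed per melody, drawn up-front from the master stream
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max, n_sets * melodies_per_set),
    nrow = n_sets
  )
  melodies <- list()
  for (s in seq_len(n_sets)) {
    for (m in seq_len(melodies_per_set)) {
      id <- sprintf("set%d_mel%02d", s - 1L, m)
      melodies[[id]] <- generate_melody(
        pitch_range = ranges[[range_pick[s]]],
        phrase_templates = phrase_templates,
        melody_id = id,
        set_index = s - 1L,
        seed = sub_seeds[s, m]
      )
    }
  }
  battery <- structure(
    list(
      melodies = melodies,
      config = config,
      master_seed = master_seed
    ),
    class = "stimulus_battery"
  )
  battery$manifest <- battery_manifest(battery)
  battery
}

#' Battery manifest with AOI/pair coding
#'
#' One row per melody: id, set, phrase order, pitch range, and which AOI
#' contains which type of note pair.
#'
#' @param battery A `stimulus_battery`.
#' @return A tibble with columns `melody_id`, `set_index`, `phrase_order`,
#'   `pitch_range`, `aoi1_pair`, `aoi2_pair`, `aoi3_pair`.
#' @export
battery_manifest <- function(battery) {
  rows <- lapply(battery$melodies, function(m) {
    tibble::tibble(
      melody_id = m$melody_id,
      set_index = m$set_index,
      phrase_order = paste(m$phrase_order, collapse = ";"),
      pitch_range = paste(m$pitch_range, collapse = ";"),
      aoi1_pair = m$aoi_note_pairs[["1"]],
      aoi2_pair = m$aoi_note_pairs[["2"]],
      aoi3_pair = m$aoi_note_pairs[["3"]]
    )
  })
  do.call(rbind, rows)
}

#' Convert a melody's note list to absolute milliseconds
#'
#' @param melody A `stimulus_melody`.
#' @param config A [timing_config()].
#' @return A tibble with `onset_ms`, `duration_ms`, `pitch` (midi number)
#'   and `velocity` columns, time zero at the first beat of bar 1.
#' @export
melody_notes_ms <- function(melody, config = timing_config()) {
  notes <- melody$notes
  tibble::tibble(
    onset_ms = beats_to_ms(notes$onset_beats, config$tempo_bpm),
    pitch = as.integer(notes$midi),
    duration_ms = beats_to_ms(notes$duration_beats, config$tempo_bpm),
    velocity = 64L
  )
}

#' Render a stimulus melody to a MIDI file and note table
#'
#' Converts the melody to absolute milliseconds and, if `path` is given,
#' writes a Standard MIDI File that round-trips through [read_performance()]
#' to the same note table.
#'
#' @param melody A `stimulus_melody`.
#' @param config A [timing_config()].
#' @param path Optional output `.mid` path.
#' @return The note table (invisibly if `path` is given).
#' @export
render_stimulus <- function(melody, config = timing_config(), path = NULL) {
  notes <- melody_notes_ms(melody, config)
  if (nrow(notes) == 0) warning("rendering an empty melody")
  if (!is.null(path)) {
    write_smf(notes, path, tempo_bpm = config$tempo_bpm)
    return(invisible(notes))
  }
  notes
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
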