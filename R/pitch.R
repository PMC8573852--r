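# Diatonic pitch arithmetic on the C-major scale.
#
# Pitches are handled in three coordinate systems:
#   * scientific pitch name ("C4", "A5"),
#   * MIDI semitone number (C4 = 60),
#   * absolute scale index: position on the C-major scale counted in scale
#     steps, with C4 = 0 (so D4 = 1, B3 = -1, C5 = 7).
# The scale index is what "one position away" means for the stimulus
# melodies' constrained pitch walks.

.C_MAJOR_LETTERS <- c("C", "D", "E", "F", "G", "A", "B")
.C_MAJOR_SEMITONES <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

#' Convert a scientific pitch name to a MIDI number
#'
#' Only natural (white-key) C-major pitches are accepted; accidentals are
#' rejected because the stimulus material is strictly diatonic.
#'
#' @param name Character vector of scientific pitch names, e.g. `"C4"`.
#' @return Integer vector of MIDI numbers (C4 = 60).
#' @export
#' @examples
#' pitch_name_to_midi(c("C4", "A5"))
pitch_name_to_midi <- function(name) {
  idx <- pitch_name_to_scale_index(name)
  scale_index_to_midi(idx)
}

#' Convert a scientific pitch name to an absolute C-major scale index
#'
#' @param name Character vector of natural pitch names.
#' @return Integer vector of scale indices with C4 = 0.
#' @export
pitch_name_to_scale_index <- function(name) {
  m <- regmatches(name, regexec("^([A-G])(-?[0-9]+)$", name))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("not a natural C-major pitch name: ",
         paste(name[bad], collapse = ", "),
         " (expected e.g. \"C4\"; accidentals are not allowed)")
  }
  letter <- vapply(m, `[`, character(1), 2L)
  octave <- as.integer(vapply(m, `[`, character(1), 3L))
  deg <- match(letter, .C_MAJOR_LETTERS) - 1L
  as.integer((octave - 4L) * 7L + deg)
}

#' Convert an absolute scale index to a scientific pitch name
#'
#' @param index Integer vector of scale indices (C4 = 0).
#' @return Character vector of pitch names.
#' @export
scale_index_to_pitch_name <- function(index) {
  index <- as.integer(index)
  octave <- 4L + index %/% 7L
  deg <- index %% 7L
  paste0(.C_MAJOR_LETTERS[deg + 1L], octave)
}

#' Convert an absolute scale index to a MIDI number
#'
#' @param index Integer vector of scale indices (C4 = 0).
#' @return Integer vector of MIDI numbers.
#' @export
scale_index_to_midi <- function(index) {
  index <- as.integer(index)
  octave <- 4L + index %/% 7L
  deg <- index %% 7L
  as.integer(12L * (octave + 1L) + .C_MAJOR_SEMITONES[deg + 1L])
}

#' Describe diatonic pitches
#'
#' @param name Character vector of natural pitch names.
#' @return A tibble with columns `name`, `midi_number` and
#'   `scale_index` (C-major position, C4 = 0).
#' @export
#' @examples
#' diatonic_pitch(c("C4", "E4", "A5"))
diatonic_pitch <- function(name) {
  idx <- pitch_name_to_scale_index(name)
  tibble::tibble(
    name = name,
    midi_number = scale_index_to_midi(idx),
    scale_index = idx
  )
}

#' Enumerate candidate five-note pitch ranges
#'
#' Builds one range per C-major scale note between `low_start` and
#' `high_start` (inclusive); each range holds five adjacent scale notes
#' ascending from its start. With the defaults this reproduces the nine
#' candidate ranges of the stimulus design, C4-D4-E4-F4-G4 up to
#' D5-E5-F5-G5-A5.
#'
#' @param low_start,high_start Natural pitch names bounding the range starts.
#' @return A list of character vectors, each of length 5.
#' @export
#' @examples
#' length(enumerate_pitch_ranges("C4", "D5"))  # 9
enumerate_pitch_ranges <- function(low_start = "C4", high_start = "D5") {
  lo <- pitch_name_to_scale_index(low_start)
  hi <- pitch_name_to_scale_index(high_start)
  if (lo > hi) stop("low_start must not be above high_start")
  lapply(seq.int(lo, hi), function(s) scale_index_to_pitch_name(s + 0:4))
}
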