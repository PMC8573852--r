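# Tempo and metric-grid arithmetic.

#' Timing configuration for stimuli and scoring
#'
#' Bundles the experimental tempo and grid parameters. The defaults match
#' the study conditions: 70 bpm, a sixteenth-note quantization grid
#' (4 subdivisions per beat), a two-bar count-in and a four-bar performance
#' in 4/4 meter.
#'
#' @param tempo_bpm Tempo in beats per minute; must be positive.
#' @param grid_division Grid subdivisions per beat; one of 1, 2, 4, 8
#'   (4 = sixteenth notes).
#' @param count_in_bars Number of count-in bars before the performance.
#' @param performance_bars Number of performed bars.
#' @param beats_per_bar Beats per bar (4/4 meter by default).
#' @return An object of class `timing_config`.
#' @export
#' @examples
#' cfg <- timing_config()
#' beats_to_ms(16, cfg$tempo_bpm)  # four 4/4 bars at 70 bpm
timing_config <- function(tempo_bpm = 70, grid_division = 4,
                          count_in_bars = 2, performance_bars = 4,
                          beats_per_bar = 4) {
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1 || tempo_bpm <= 0) {
    stop("tempo_bpm must be a single positive number")
  }
  if (!grid_division %in% c(1, 2, 4, 8)) {
    stop("grid_division must be one of 1, 2, 4, 8")
  }
  structure(
    list(
      tempo_bpm = tempo_bpm,
      grid_division = as.integer(grid_division),
      count_in_bars = as.integer(count_in_bars),
      performance_bars = as.integer(performance_bars),
      beats_per_bar = as.integer(beats_per_bar)
    ),
    class = "timing_config"
  )
}

#' Convert musical beats to milliseconds
#'
#' Exact conversion `beats * 60000 / tempo_bpm`; no rounding is applied, so
#' the result can be aggregated before integer reporting. At 70 bpm, 8 beats
#' give 6857 ms and 16 beats 13714 ms once rounded.
#'
#' @param beats Numeric vector of beat positions/durations; must be >= 0.
#' @param tempo_bpm Tempo in beats per minute.
#' @return Numeric vector of milliseconds (full precision).
#' @export
beats_to_ms <- function(beats, tempo_bpm = 70) {
  if (tempo_bpm <= 0) stop("tempo_bpm must be positive")
  if (any(beats < 0)) stop("beats must be non-negative")
  beats * 60000 / tempo_bpm
}

#' Convert milliseconds to beats
#'
#' @param ms Numeric vector of milliseconds.
#' @param tempo_bpm Tempo in beats per minute.
#' @return Numeric vector of beats.
#' @export
ms_to_beats <- function(ms, tempo_bpm = 70) {
  if (tempo_bpm <= 0) stop("tempo_bpm must be positive")
  ms * tempo_bpm / 60000
}

#' Width of one grid step in milliseconds
#'
#' @param config A [timing_config()].
#' @return A single number: `60000 / (tempo_bpm * grid_division)` ms
#'   (214.29 ms for sixteenths at 70 bpm).
#' @export
grid_step_ms <- function(config = timing_config()) {
  60000 / (config$tempo_bpm * config$grid_division)
}
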