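# One-bar rhythmic phrase templates.
#
# Each stimulus melody concatenates the four phrase types in random order.
# A phrase spans exactly one 4/4 bar; its first two sounding events, starting
# at beat 0 (directly after the barline), are the defining note pair; the
# phrase ends with a rest; only eighth (0.5 beat) and quarter (1 beat) values
# occur. The filler notes between the pair and the final rest are
# reconstructions under those constraints, shipped as defaults and
# replaceable via the `phrase_templates` argument of [generate_melody()].

#' The four note-pair types
#'
#' @return Character vector of the four pair types, ordered by the duration
#'   pattern of the opening two notes.
#' @export
pair_types <- function() {
  c("eighth-eighth", "eighth-quarter", "quarter-eighth", "quarter-quarter")
}

#' Default one-bar rhythmic phrase templates
#'
#' @return A named list (one element per [pair_types()] value) of tibbles
#'   with columns `onset_beats`, `duration_beats`, `is_rest`.
#' @export
#' @examples
#' default_phrase_templates()[["eighth-eighth"]]
default_phrase_templates <- function() {
  tmpl <- list(
    "eighth-eighth" = list(
      onset = c(0, 0.5, 1, 2, 3, 3.5),
      dur   = c(0.5, 0.5, 1, 1, 0.5, 0.5),
      rest  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    "eighth-quarter" = list(
      onset = c(0, 0.5, 1.5, 2, 3),
      dur   = c(0.5, 1, 0.5, 1, 1),
      rest  = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    "quarter-eighth" = list(
      onset = c(0, 1, 1.5, 2, 3),
      dur   = c(1, 0.5, 0.5, 1, 1),
      rest  = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    "quarter-quarter" = list(
      onset = c(0, 1, 2, 3),
      dur   = c(1, 1, 1, 1),
      rest  = c(FALSE, FALSE, FALSE, TRUE)
    )
  )
  out <- lapply(names(tmpl), function(nm) {
    x <- tmpl[[nm]]
    ph <- tibble::tibble(
      onset_beats = x$onset,
      duration_beats = x$dur,
      is_rest = x$rest
    )
    validate_phrase(ph, nm)
    ph
  })
  names(out) <- names(tmpl)
  out
}

#' Validate a rhythmic phrase template
#'
#' Checks the structural invariants of a one-bar phrase: a 4-beat span with
#' contiguous events, only eighth/quarter values, the defining note pair as
#' the first two sounding events starting at beat 0, and a terminal rest.
#'
#' @param phrase A tibble with columns `onset_beats`, `duration_beats`,
#'   `is_rest`.
#' @param pair_type The pair type the phrase must open with.
#' @return The phrase, invisibly; errors if any invariant is violated.
#' @export
validate_phrase <- function(phrase, pair_type) {
  pair_type <- match.arg(pair_type, pair_types())
  n <- nrow(phrase)
  if (n < 3) stop("phrase must have at least two notes and one rest")
  ends <- phrase$onset_beats + phrase$duration_beats
  if (phrase$onset_beats[1] != 0 || abs(ends[n] - 4) > 1e-9 ||
      any(abs(phrase$onset_beats[-1] - ends[-n]) > 1e-9)) {
    stop("phrase events must tile one 4-beat bar contiguously")
  }
  if (!all(phrase$duration_beats %in% c(0.5, 1))) {
    stop("phrase may contain only eighth (0.5) and quarter (1) values")
  }
  if (!phrase$is_rest[n]) stop("phrase must end with a rest")
  sounding <- which(!phrase$is_rest)
  if (length(sounding) < 2 || sounding[1] != 1L || sounding[2] != 2L) {
    stop("the defining note pair must be the first two events at beat 0")
  }
  want <- switch(pair_type,
    "eighth-eighth"   = c(0.5, 0.5),
    "eighth-quarter"  = c(0.5, 1),
    "quarter-eighth"  = c(1, 0.5),
    "quarter-quarter" = c(1, 1)
  )
  if (!isTRUE(all.equal(phrase$duration_beats[1:2], want))) {
    stop("opening note pair durations do not match pair type ", pair_type)
  }
  invisible(phrase)
}
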