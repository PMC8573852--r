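# The scoring core: quantization, onset matching, pitch scoring and
# accuracy aggregation.

test_that("quantization reproduces the sixteenth-grid worked examples", {
  cfg <- timing_config()
  q <- quantize_onset(840, cfg)
  expect_equal(q$grid_index, 4L)
  expect_equal(round(q$quantized_onset_ms), 857)
  expect_equal(quantize_onset(0, cfg)$grid_index, 0L)
  q2 <- quantize_onset(1000, cfg)
  expect_equal(q2$grid_index, 5L)
  expect_equal(round(q2$quantized_onset_ms), 1071)
})

test_that("quantization is idempotent, tie-up, and matches brute force", {
  cfg <- timing_config()
  step <- grid_step_ms(cfg)
  # exact midpoint rounds to the later grid index
  expect_equal(quantize_onset(step / 2, cfg)$grid_index, 1L)
  # slightly-early onsets snap to grid 0; earlier ones clamp with warning
  expect_equal(quantize_onset(-step / 4, cfg)$grid_index, 0L)
  expect_warning(q <- quantize_onset(-step, cfg), "clamped")
  expect_equal(q$grid_index, 0L)
  set.seed(11)
  onsets <- runif(500, 0, beats_to_ms(16, cfg$tempo_bpm))
  q <- quantize_onset(onsets, cfg)
  # idempotence
  expect_equal(quantize_onset(q$quantized_onset_ms, cfg)$grid_index,
               q$grid_index)
  # brute-force argmin over all grid onsets in the melody span
  grid <- (0:80) * step
  brute <- vapply(onsets, function(o) which.min(abs(grid - o)) - 1L,
                  integer(1))
  agree <- q$grid_index == brute |
    abs(abs(onsets - grid[brute + 1]) - step / 2) < 1e-9  # midpoint ties
  expect_true(all(agree))
})

test_that("onset matching follows the grid comparison rule", {
  stim <- quarter_note_stimulus()
  cfg <- timing_config()
  # performed onsets 10, 880, 1300, 2400 -> grids 0, 4, 6, 11 vs {0,4,8,12}
  perf <- performance_at_beats(c(0, 1, 2, 3), c("C4", "E4", "G4", "C5"),
                               offset_ms = c(10, 23, -414, -171))
  s <- score_performance(perf, stim, cfg)
  expect_equal(s$notes$onset_correct, c(TRUE, TRUE, FALSE, FALSE))
  # +300 ms shifts every grid index off the stimulus grid
  perf_shift <- perf
  perf_shift$onset_ms <- beats_to_ms(0:3, 70) + 300
  s2 <- score_performance(perf_shift, stim, cfg)
  expect_equal(s2$notes$grid_index, c(1L, 5L, 9L, 13L))
  expect_false(any(s2$notes$onset_correct))
  expect_equal(s2$melody$onset_accuracy, 0)
  expect_true(is.na(s2$melody$pitch_accuracy))
})

test_that("a stimulus position is claimed by the earliest performed note", {
  stim <- quarter_note_stimulus()
  # two notes quantizing to grid 0: only the earlier is onset-correct
  perf <- data.frame(onset_ms = c(5, 80), pitch = c(60L, 60L),
                     duration_ms = 100)
  s <- score_performance(perf, stim)
  expect_equal(s$notes$onset_correct, c(TRUE, FALSE))
  expect_equal(s$melody$n_onset_correct, 1)
})

test_that("pitch is scored only at correct onsets, by exact MIDI match", {
  stim <- quarter_note_stimulus()
  perf <- performance_at_beats(c(0, 1, 2, 3), c("C4", "E4", "G4", "C5"))
  s <- score_performance(perf, stim)
  expect_true(all(s$notes$pitch_correct))
  # one semitone off and one octave off are both wrong
  perf2 <- perf
  perf2$pitch[2] <- perf2$pitch[2] + 1L
  perf2$pitch[3] <- perf2$pitch[3] + 12L
  s2 <- score_performance(perf2, stim)
  expect_equal(s2$notes$pitch_correct, c(TRUE, FALSE, FALSE, TRUE))
  # incorrect-onset notes have undefined pitch correctness
  perf3 <- performance_at_beats(c(0, 1.25, 2, 3), c("C4", "E4", "G4", "C5"))
  s3 <- score_performance(perf3, stim)
  expect_true(is.na(s3$notes$pitch_correct[2]))
})

test_that("melody accuracy fractions follow the worked example", {
  stim <- quarter_note_stimulus()
  perf <- performance_at_beats(c(0, 1, 2, 3), c("C4", "F4", "G4", "C5"),
                               offset_ms = c(10, 23, -414, -171))
  s <- score_performance(perf, stim)
  expect_equal(s$melody$onset_accuracy, 0.5)
  expect_equal(s$melody$pitch_accuracy, 0.5)
  # perfect performance
  s2 <- score_performance(
    performance_at_beats(0:3, c("C4", "E4", "G4", "C5")), stim)
  expect_equal(s2$melody$onset_accuracy, 1)
  expect_equal(s2$melody$pitch_accuracy, 1)
  # count ordering invariant
  expect_true(s$melody$n_pitch_correct <= s$melody$n_onset_correct)
  expect_true(s$melody$n_onset_correct <= s$melody$n_performed)
})

test_that("perturbing k onsets off-grid reduces the correct count by k", {
  b <- generate_battery(master_seed = 13)
  cfg <- timing_config()
  step <- grid_step_ms(cfg)
  for (trial in 1:10) {
    m <- b$melodies[[trial]]
    notes <- as.data.frame(render_stimulus(m, cfg))
    stim_grids <- stimulus_grid(m, cfg)$grid_index
    # pick positions whose +1-step neighbour holds no stimulus note
    movable <- which(!(stim_grids + 1L) %in% stim_grids)
    k <- min(3L, length(movable))
    idx <- movable[seq_len(k)]
    notes$onset_ms[idx] <- notes$onset_ms[idx] + step
    s <- score_performance(notes, m, cfg)
    expect_equal(s$melody$n_onset_correct, nrow(notes) - k)
  }
})

test_that("pair accuracy restricts scoring to the coded note pairs", {
  b <- generate_battery(master_seed = 2)
  cfg <- timing_config()
  m <- b$melodies[[1]]
  notes <- as.data.frame(render_stimulus(m, cfg))
  s <- score_performance(notes, m, cfg)
  expect_equal(nrow(s$pairs), 3)
  expect_equal(s$pairs$onset_accuracy, rep(1, 3))
  expect_equal(s$pairs$pitch_accuracy, rep(1, 3))
  expect_equal(s$pairs$pair_type, m$phrase_order[2:4])

  # degrade AOI 1's pair (first two sounding notes of bar 2): one onset
  # moved a beat off-grid, the surviving note's pitch wrong
  pair_rows <- which(m$notes$bar == 2 & m$notes$is_pair_note)
  notes2 <- notes
  notes2$onset_ms[pair_rows[1]] <- notes2$onset_ms[pair_rows[1]] + 4 * grid_step_ms(cfg)
  notes2$pitch[pair_rows[2]] <- notes2$pitch[pair_rows[2]] + 1L
  s2 <- score_performance(notes2, m, cfg)
  expect_equal(s2$pairs$onset_accuracy[1], 0.5)
  expect_equal(s2$pairs$pitch_accuracy[1], 0)

  # pair entirely absent -> onset 0, pitch undefined
  notes3 <- notes[-pair_rows, ]
  s3 <- score_performance(notes3, m, cfg)
  expect_equal(s3$pairs$onset_accuracy[1], 0)
  expect_true(is.na(s3$pairs$pitch_accuracy[1]))
})

test_that("empty performances yield NA accuracies", {
  stim <- quarter_note_stimulus()
  s <- score_performance(data.frame(onset_ms = numeric(0),
                                    pitch = integer(0)), stim)
  expect_equal(s$melody$n_performed, 0)
  expect_true(is.na(s$melody$onset_accuracy))
  expect_true(is.na(s$melody$pitch_accuracy))
})
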