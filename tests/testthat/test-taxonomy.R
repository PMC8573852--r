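# Rhythm-error taxonomy: labels, deviations, partition invariants and the
# exhaustive assignment oracle.

test_that("an identical performance is all-correct with no deviations", {
  b <- generate_battery(master_seed = 4)
  m <- b$melodies[[2]]
  s <- score_performance(render_stimulus(m), m)
  cls <- classify_errors(s)
  expect_equal(cls$summary$n_correct, nrow(m$notes))
  expect_equal(cls$summary$n_added + cls$summary$n_early +
                 cls$summary$n_late + cls$summary$n_skipped, 0)
  expect_true(is.na(cls$summary$mean_abs_onset_deviation_beats))
})

test_that("an extra note between beats is labelled added", {
  stim <- quarter_note_stimulus()
  perf <- performance_at_beats(c(0, 1, 1.5, 2, 3),
                               c("C4", "E4", "E4", "G4", "C5"))
  cls <- classify_errors(score_performance(perf, stim))
  perf_lab <- cls$table$label[cls$table$role == "performed"]
  expect_equal(perf_lab, c("correct", "correct", "added", "correct",
                           "correct"))
  expect_equal(cls$summary$n_added, 1)
  expect_equal(cls$summary$n_skipped, 0)
})

test_that("an unperformed note with correct neighbours is skipped", {
  stim <- quarter_note_stimulus()
  perf <- performance_at_beats(c(0, 1, 3), c("C4", "E4", "C5"))
  cls <- classify_errors(score_performance(perf, stim))
  stim_lab <- cls$table[cls$table$role == "stimulus", ]
  expect_equal(stim_lab$label, c("matched", "matched", "skipped", "matched"))
  expect_true(stim_lab$skipped_strict[3])
  expect_equal(cls$summary$n_skipped, 1)
  expect_equal(cls$summary$n_skipped_strict, 1)
})

test_that("a note one sixteenth early pairs with deviation -0.25 beats", {
  stim <- quarter_note_stimulus()
  perf <- performance_at_beats(c(0, 1, 1.75, 3), c("C4", "E4", "G4", "C5"))
  cls <- classify_errors(score_performance(perf, stim))
  early <- cls$table[cls$table$role == "performed" &
                       cls$table$label == "early", ]
  expect_equal(nrow(early), 1)
  expect_equal(early$onset_deviation_beats, -0.25)
  expect_equal(early$pitch_deviation_semitones, 0L)  # same pitch
  # late counterpart
  perf2 <- performance_at_beats(c(0, 1, 2.5, 3), c("C4", "E4", "A4", "C5"))
  cls2 <- classify_errors(score_performance(perf2, stim))
  late <- cls2$table[cls2$table$role == "performed" &
                       cls2$table$label == "late", ]
  expect_equal(late$onset_deviation_beats, 0.5)
  expect_equal(late$pitch_deviation_semitones, 69L - 67L)
})

test_that("unmatched notes beyond the pairing radius become added/skipped", {
  stim <- quarter_note_stimulus()
  # stimulus note at beat 2 unplayed; a stray note at beat 3.5 lies 1.5
  # beats away, beyond the default one-beat pairing radius
  perf <- performance_at_beats(c(0, 1, 3, 3.5), c("C4", "E4", "C5", "G4"))
  cls <- classify_errors(score_performance(perf, stim))
  perf_lab <- cls$table$label[cls$table$role == "performed"]
  expect_equal(perf_lab[4], "added")
  stim_lab <- cls$table$label[cls$table$role == "stimulus"]
  expect_equal(stim_lab[3], "skipped")
  # a wider radius pairs them instead
  cls2 <- classify_errors(score_performance(perf, stim), radius_beats = 2)
  expect_equal(cls2$table$label[cls2$table$role == "performed"][4], "late")
})

test_that("labels partition performed and stimulus notes", {
  set.seed(21)
  b <- generate_battery(master_seed = 5)
  cfg <- timing_config()
  for (trial in 1:20) {
    m <- b$melodies[[sample.int(48, 1)]]
    sim <- simulate_performance(
      m, cfg,
      performer_params(onset_jitter_sd_ms = 150, p_skip = 0.15,
                       p_add = 0.15, p_pitch_error = 0.1))
    s <- score_performance(sim$record, m, cfg)
    cls <- classify_errors(s, cfg)
    sm <- cls$summary
    expect_equal(sm$n_correct + sm$n_added + sm$n_early + sm$n_late,
                 sm$n_performed)
    stim_rows <- cls$table[cls$table$role == "stimulus", ]
    expect_equal(sum(stim_rows$label == "matched") +
                   sum(stim_rows$label %in% c("early", "late")) +
                   sm$n_skipped,
                 sm$n_stimulus)
    perf_rows <- cls$table[cls$table$role == "performed", ]
    expect_true(all(table(perf_rows$label) >= 0))
    # every note carries exactly one label
    expect_false(any(is.na(perf_rows$label)))
    expect_false(any(is.na(stim_rows$label)))
    # deviations defined exactly for early/late performed notes
    el <- perf_rows$label %in% c("early", "late")
    expect_true(all(!is.na(perf_rows$onset_deviation_beats[el])))
    expect_true(all(is.na(perf_rows$onset_deviation_beats[!el])))
    expect_true(all(abs(perf_rows$onset_deviation_beats[el]) >= 0.25 - 1e-9))
  }
})

test_that("pairing equals the exhaustive minimum-deviation assignment", {
  cfg <- timing_config()
  radius_steps <- 1 * cfg$grid_division
  set.seed(31)
  n_checked <- 0
  for (case in 1:200) {
    n_s <- sample.int(4, 1)
    n_p <- sample.int(4, 1)
    grids <- sample.int(20, n_s + n_p) - 1L  # distinct grid positions
    s_grids <- sort(grids[seq_len(n_s)])
    p_grids <- sort(grids[n_s + seq_len(n_p)])
    oracle <- exhaustive_assignment(s_grids, p_grids, radius_steps)

    # build a trial whose unmatched grids are exactly these: stimulus notes
    # at s_grids, performed notes at p_grids (all off the stimulus grid)
    stim <- melody_from_notes(data.frame(
      onset_beats = s_grids / cfg$grid_division,
      duration_beats = 0.25, midi = 60L))
    perf <- data.frame(
      onset_ms = p_grids * grid_step_ms(cfg),
      pitch = 60L, duration_ms = 50)
    cls <- classify_errors(score_performance(perf, stim, cfg), cfg,
                           radius_beats = 1)
    got_pairs <- sum(cls$table$label %in% c("early", "late") &
                       cls$table$role == "performed")
    got_cost <- sum(abs(cls$table$onset_deviation_beats), na.rm = TRUE) *
      cfg$grid_division
    expect_equal(got_pairs, oracle$pairs)
    expect_equal(got_cost, oracle$cost)
    if (oracle$unique) {
      got_set <- pairing_set_string(cls$table, seq_len(n_s), seq_len(n_p))
      expect_equal(got_set, oracle$set)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)  # enough unique-optimum instances exercised
})

test_that("error summary counts an injected number of skips exactly", {
  b <- generate_battery(master_seed = 6)
  m <- b$melodies[[3]]
  notes <- as.data.frame(render_stimulus(m))
  drop <- c(4, 9)
  cls <- classify_errors(score_performance(notes[-drop, ], m))
  expect_equal(cls$summary$n_skipped, 2)
  expect_equal(cls$summary$n_correct, nrow(notes) - 2)
})
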