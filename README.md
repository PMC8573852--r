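# sightscore

Tools for scoring recorded musical **sight-reading performances** against
their stimulus melodies, classifying rhythm errors, and quality-controlling
the accompanying **eye-movement data** — the analysis chain of a typical
sight-reading eye-tracking experiment, exercisable end to end on synthetic
data.

The package is aimed at researchers in music cognition and reading research
who record MIDI performances of notated melodies at a fixed tempo (with a
metronome) and track the performer's gaze over the score.

## What it computes

**Performance scoring.** Each performed note onset $t$ (ms, time zero at
the first performed beat) is quantized to the nearest position of a metric
grid with step $\Delta = 60000/(\text{bpm}\times\text{division})$ —
sixteenth notes at 70 bpm by default, $\Delta = 214.29$ ms:

$$k = \lfloor t/\Delta + \tfrac12 \rfloor .$$

A performed note is *onset-correct* iff its grid index equals an unclaimed
stimulus note's grid index; pitch is then scored by exact MIDI-number
comparison for onset-correct notes only (they alone have a clear reference
pitch). Per melody:

- onset accuracy = onset-correct notes / performed notes,
- pitch accuracy = pitch-correct notes / onset-correct notes
  (`NA` when no onset is correct),

and the same fractions per coded note pair (AOI level).

**Rhythm-error taxonomy.** Beyond binary correctness, notes are classified
as **correct / added / skipped / early / late**. Unmatched performed and
stimulus notes are paired by an exact minimum-deviation assignment within a
one-beat radius; early/late pairs get continuous deviations — onset in
beats (negative = early) and pitch in semitones.

**Stimulus generation.** Four sets of twelve 4-bar melodies (48 in total)
built from four one-bar rhythmic phrases (opening note pairs:
eighth–eighth, eighth–quarter, quarter–eighth, quarter–quarter), each
appearing once per melody in random order, with pitches from a five-note
C-major range following a constrained walk (no step larger than one scale
position). Melodies render to Standard MIDI Files and CSV note tables.

**Gaze QC.** Trial exclusions on fixation measures (count, total gaze
duration, fixations outside the valid area), data-point exclusions that
blank only saccade measures, AOI assignment with first-/second-pass
fixation counts and gaze durations, and visual-angle geometry
($2°$ at 60 cm $= 2.1$ cm on screen).

## Worked example

Score a 4-note performance of a four-quarter-note stimulus (C4 E4 G4 C5 at
beats 0–3, 70 bpm). The performer plays the first note 10 ms late, the
second at 880 ms with a wrong pitch (F4 for E4), and the last two well off
the grid:

```r
library(sightscore)

stim <- melody_from_notes(data.frame(
  onset_beats = 0:3, duration_beats = 1,
  pitch = c("C4", "E4", "G4", "C5")))

perf <- data.frame(
  onset_ms = c(10, 880, 1300, 2400),
  pitch = pitch_name_to_midi(c("C4", "F4", "G4", "C5")),
  duration_ms = 200)

s <- score_performance(perf, stim)
s$notes[, c("onset_ms", "pitch", "grid_index", "onset_correct", "pitch_correct")]
#>   onset_ms pitch grid_index onset_correct pitch_correct
#> 1       10    60          0 TRUE          TRUE
#> 2      880    65          4 TRUE          FALSE
#> 3     1300    67          6 FALSE         NA
#> 4     2400    72         11 FALSE         NA

s$melody[, c("n_performed", "n_onset_correct", "onset_accuracy", "pitch_accuracy")]
#>   n_performed n_onset_correct onset_accuracy pitch_accuracy
#> 1           4               2            0.5            0.5
```

Notes 1 and 2 quantize onto stimulus grid positions 0 and 4 (onset-correct;
note 2's pitch is wrong), notes 3 and 4 land on grids 6 and 11 where no
stimulus note sits, so onset accuracy is 2/4 = 0.50 and pitch accuracy
1/2 = 0.50. The error classifier then explains the two incorrect onsets:

```r
cls <- classify_errors(s)
subset(cls$table, role == "performed",
       c(note_index, grid_index, label, onset_deviation_beats))
#>   note_index grid_index label   onset_deviation_beats
#> 1          1          0 correct                 NA
#> 2          2          4 correct                 NA
#> 3          3          6 early                   -0.5
#> 4          4         11 early                   -0.25
```

Both stray notes pair with their nearest unplayed stimulus positions
(grids 8 and 12): each was played early, by half a beat and a quarter beat.

Generate and render the full stimulus battery, or simulate a noisy
performer:

```r
b <- generate_battery(master_seed = 1)    # 48 melodies + manifest
sim <- simulate_performance(b$melodies[[1]],
                            params = performer_params(p_skip = 0.2, seed = 1))
classify_errors(score_performance(sim$record, b$melodies[[1]]))$summary
```

A thin command-line wrapper (`exec/sightscore`) exposes the same pipeline
as subcommands: `generate-stimuli`, `simulate`, `score`, `classify-errors`,
`gaze-qc`, `report`.

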