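---
title: "Scoring sight-reading performances: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sight-reading performances: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sightscore)
```

## The scoring model

`sightscore` analyses recordings of musicians sight-reading short notated
melodies on a MIDI instrument at a fixed tempo. The stimulus melody is known
exactly — every note has a metric onset in beats and a diatonic pitch — so a
performance can be scored note by note against it. Scoring proceeds in three
steps.

**1. Quantization.** Each performed onset (in ms, with time zero at the
first beat of the performance) is moved to the closest position on a metric
grid with `grid_division` subdivisions per beat. At the default 70 bpm with
a sixteenth-note grid, one grid step is $60000 / (70 \times 4) = 214.29$ ms,
so a note played at 840 ms snaps to grid index 4 at $857.14$ ms. The grid
index is

$$k = \left\lfloor \frac{t}{\Delta} + \tfrac12 \right\rfloor,
\qquad \Delta = \frac{60000}{\text{bpm} \times \text{division}},$$

which rounds an exact midpoint *up* to the later grid position. The rule is
arbitrary at a set of measure zero but has to be fixed for reproducibility;
half-up is the least surprising convention and is what `floor(x + 0.5)`
gives. Onsets up to half a grid step before zero snap to grid 0 (a slightly
anticipated first note is still a performance of it); anything earlier is
clamped to 0 with a warning, since it cannot belong to the scored melody.
The grid is bounded at the last stimulus onset plus one bar so that trailing
stray notes still receive finite indices.

**2. Onset matching.** A performed note is *onset-correct* iff its grid
index equals the grid index of a stimulus note that has not already been
claimed by an earlier performed note. The claim order is by raw onset,
left to right: when two performed notes quantize to the same stimulus
position, the earlier one is correct and the later one is surplus. Without
this rule the number of correct notes could exceed the number of stimulus
notes and accuracy fractions could leave $[0, 1]$.

**3. Pitch scoring.** Only onset-correct notes have an unambiguous
reference pitch, so pitch is scored only for them, by exact MIDI-number
comparison — an octave error is as wrong as a semitone error. Notes with
incorrect onsets carry `NA` for pitch correctness.

Per melody,

$$\text{onset accuracy} = \frac{\#\,\text{onset-correct}}{\#\,\text{performed}},
\qquad
\text{pitch accuracy} = \frac{\#\,\text{pitch-correct}}{\#\,\text{onset-correct}},$$

with an *undefined* (`NA`) pitch accuracy when no onset is correct — an
empty denominator is never reported as 0 or 1, because both would fabricate
information. The same formulas applied to the two stimulus notes of a coded
note pair give the pair-level (AOI-level) accuracies, with onset accuracy
taken over the pair's two stimulus positions.

## The rhythm-error taxonomy

Binary correctness hides *how* a note is wrong. The classifier distinguishes
four rhythm errors: **added** (surplus performed notes), **skipped**
(unperformed stimulus notes), **early** and **late** (a performed note
displaced from its stimulus position). Early/late notes additionally get
continuous deviations: onset deviation in beats (negative = early) and pitch
deviation in semitones, which restores a pitch measure for notes whose onset
is wrong.

After onset matching, the unmatched stimulus notes and unmatched performed
notes must be paired before the residue can be labelled. The pairing rule
implemented is an *exact assignment*: among pairings whose members lie
within a configurable radius of each other (default one beat), it maximises
the number of pairs and, among those, minimises the total absolute grid
deviation, breaking remaining ties toward pairing earlier notes. Because
the cost is an absolute distance on a line, an optimal assignment can
always be chosen non-crossing, so a dynamic program over the two sorted
sequences computes it in $O(nm)$. A simpler greedy scan (each unmatched
stimulus note grabs its nearest free performed note, left to right) was
considered and rejected: it is provably suboptimal — with stimulus residue
at grids $\{0, 5\}$ and performed residue at $\{4, 7\}$ it pairs
$(5,4),(0,7)$ at total deviation 8 where the unique optimum
$(0,4),(5,7)$ costs 6 — and an error taxonomy that attributes a note to the
wrong target misstates both deviations. The test suite checks the dynamic
program against an exhaustive enumeration on small instances.

The pairing radius exists because unconstrained nearest-pairing across bars
is musically meaningless: a stray note three bars away from an unplayed one
is an addition, not a very late performance of it. One beat is the default
because beyond it a displaced note crosses other metric positions and its
intended target becomes genuinely ambiguous. The literal reading of
"skipped" — an unperformed note whose two neighbours are both
onset-correct — is stricter than the radius-based label on clustered
errors, so it is reported alongside as the `skipped_strict` flag rather
than replacing the label.

## Stimulus generation

The generated battery reproduces the experimental design: 4 sets × 12
melodies, each melody four 4/4 bars, each bar one of the four one-bar
rhythmic phrases (defined by its opening note pair: eighth–eighth,
eighth–quarter, quarter–eighth, quarter–quarter) in random order with every
phrase appearing exactly once. Pitches come from one of nine candidate
five-note C-major ranges (starting on each scale note from C4 to D5); one
range is drawn per set, and within a melody pitches follow a constrained
walk — the first drawn uniformly from the range, each later one drawn
uniformly from the range notes at most one scale position away (repetition
allowed, so at an interior note the choice set has three elements and at a
range boundary two). This keeps intervallic leaps out of the material while
making the continuation unpredictable.

The published design fixes the phrases' constraints — the note pair opens
the bar directly after the barline, the bar ends with a rest, and only
eighth and quarter values occur — but not the exact filler between pair and
rest, which is available only as notation images. The templates shipped in
`default_phrase_templates()` are therefore documented reconstructions
satisfying all stated constraints, and callers can substitute their own
via the `phrase_templates` argument; every invariant check and scoring
path treats templates as data.

Randomness is driven by one master seed: the battery function draws one
sub-seed per melody (and the per-set range choices) from the master stream
up front, so the same master seed reproduces the battery byte-identically
while individual melodies remain independently reproducible from their
sub-seeds.

## Screen geometry and AOIs

All geometry is handled in centimetres on the stimulus image (1920 × 1080
px = 49.92 × 28.08 cm, so both axes share one px↔cm scale; converters are
provided because fixation tables arrive in either unit). The staff (27.3 cm
wide, 0.78 cm high: a 1.3 cm clef/meter block plus four 6.5 cm bars) is
centred on the image; the 32.23 × 5.98 cm valid area is centred on the
staff. AOIs are 2.24 × 2.11 cm — comfortably above the 1.5° visual-angle
minimum for AOI sizes, which is 1.57 cm at the 60 cm viewing distance
(2° ≈ 2.1 cm is the high-acuity foveal region). Exact AOI pixel origins are
not published, so AOIs are derived from the geometry: each starts at its
bar's barline (the note pair of interest appears directly after it) on bars
2–4, vertically centred on the staff; bar 1 carries no AOI because its
content is previewed during the count-in. Overlap is rejected at
construction time.

## Gaze quality control

Inputs are pre-detected fixation/saccade event tables; event detection from
raw gaze samples is out of scope. Three exclusion tiers apply, all with
thresholds in `qc_thresholds()`:

* **Trials** are excluded on fixation measures: fewer than 4 or more than
  40 fixations, total gaze duration below 4571 ms or above 13714 ms (the
  reading time of a four-bar melody at 70 bpm), or more than 5 fixations
  outside the valid area. Each trial is flagged with *every* violated
  criterion; the criteria are evaluated as a set of independent predicates,
  so the flags cannot depend on application order. One published criterion,
  "fixations outside valid area < 0", is impossible for a well-formed
  count; it is implemented as a data-integrity check — a negative recorded
  count marks a corrupt record and excludes the trial.
* **Saccade data points**: when a retained trial has fewer than 3 saccades,
  a total forward-saccade distance under 13 cm (less than half the staff),
  or fixation and saccade counts differing by more than 8, only its saccade
  measures are blanked; adaptive event detection can miss saccades in noisy
  data while still detecting fixations robustly, so the fixation measures
  remain usable.
* **AOI records** with more than 6 fixations or over 4000 ms of gaze are
  treated as measurement noise and blanked.

First/second-pass measures have no published definition, so the package
uses the standard reading-research convention: within a trial's temporal
fixation sequence, each AOI's fixations decompose into maximal runs of
consecutive in-AOI fixations; the first run is the first pass, the run at
the next re-entry the second pass. This conserves counts and durations by
construction (`n_first + n_second + n_later = n_fixations`). AOI membership
is point-in-rectangle with left/top edges inclusive and right/bottom edges
exclusive, so adjacent rectangles partition the plane. An AOI never fixated
is `missing`, not zero: a skipped AOI provides no reading-time information.

## The synthetic performer and gaze generator

The simulator exists so the whole pipeline is testable with known ground
truth. A performer is parameterised by Gaussian onset jitter (SD in ms,
truncated so onsets stay non-negative), a constant delay, a pitch
substitution probability (offsets uniform on ±1..±`range` semitones, never
zero, emulating adjacent-key errors), a per-note skip probability and a
per-gap insertion probability with pitches drawn from the melody's range.
This reproduces exactly the error structure the accuracy measures and the
taxonomy assume — which is the point: with `p_skip = 0.2` and no other
errors the taxonomy must recover the skip count exactly, and onset accuracy
must fall monotonically in jitter SD because larger jitter crosses grid
midpoints more often ($P(|N(0,\sigma)| < \Delta/2)$ is decreasing in
$\sigma$). What the simulator does **not** model: serial dependence of
errors, tempo drift, expressive timing, hand-position drift, or any
cognitive account of sight-reading. Passing recovery tests therefore
validates the measurement chain, not any claim about real performers.

Gaze scans move left to right over evenly spaced staff targets, regress to
an earlier target with probability `p_regression`, and add isotropic
Gaussian coordinate noise; durations are truncated-Gaussian. Defaults
(about 4 fixations per bar at 600 ms) put clean trials inside the retention
window of the QC defaults so that injected violations — not baseline
noise — drive exclusion counts in tests.

## Numerical and interface choices

* Time is kept in full double precision throughout; rounding to integer
  milliseconds happens only at reporting time (857, 6857, 13714 are
  reporting-time roundings of 857.14…, 6857.14…, 13714.28…).
* The performance time anchor defaults to `count_in_end`: recordings that
  include the two-bar count-in (8 beats = 6857 ms at 70 bpm) are shifted so
  time zero is the first performed beat, the frame all scoring assumes.
  Files that already start at the performance use `anchor = "file_start"`.
* Standard MIDI File support is a minimal format-0/1 reader/writer (note
  on/off, running status, set-tempo meta events, tempo-map tick→ms
  conversion); overlapping note-ons close the earlier note at the later
  onset with a warning, and durations survive write/read round trips to
  within half a tick (~0.9 ms at 480 ppq, 70 bpm).
* Empty inputs yield header-only output tables and `NA` accuracies, never
  silent zeros.

## Validation scale

The shipped test suite validates melody invariants over 1000 generated
melodies, quantization against a brute-force nearest-grid search over
10,000 random onsets, the error-pairing dynamic program against exhaustive
enumeration on ~350 random small instances (≤ 6 × 6 notes), skip-rate
recovery over ~10,000 simulated notes, and jitter/pitch-error calibration
over full 48-melody batteries per condition. These sizes give binomial
standard errors of a few tenths of a percentage point on the recovered
rates while keeping a full run around a minute and a half.

## Known limitations

* Alignment is grid-based, not sequence-based: a performance at a globally
  wrong tempo scores near zero instead of being time-warped onto the
  stimulus. That is the intended measurement model for metronome-paced
  performance, not a general transcription aligner.
* Duration and velocity are carried through I/O but not scored.
* The phrase fillers are reconstructions (see above); analyses that depend
  on the exact filler rhythm should supply their own templates.
* MusicXML export and graphical score rendering are out of scope.
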