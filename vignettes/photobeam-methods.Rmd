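---
title: "photobeam: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{photobeam: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photobeam)
```

photobeam is a virtual closed-loop light-stimulation rig for *Drosophila*
housed in multi-beam activity tubes, plus the behavioural analyses such rigs
support. This vignette explains the data model, the light-protocol engine,
the generative fly model and the statistical procedures, together with the
numerical conventions and the design choices that were genuinely open.

## The data model

The instrument being emulated is a bank of 16 tube slots, each tube watched
by 17 infrared beams. Two channels are recorded per fly per second — the
shortest resolution the hardware reports:

* **counts** — the number of beam interruptions in that second, the standard
  locomotion unit for tube monitors;
* **position** — the index of the beam nearest the fly at the end of the
  second (1-based).

`activity_trace()` holds one fly's session. Because a fly cannot change its
nearest beam by more cells than beams it interrupted, a physically sound
trace satisfies `counts[k] >= |position[k] - position[k-1]|` for every
second. Real hardware glitches, so the reader (`read_activity_csv()`)
reports violations as row-indexed warnings rather than refusing the file;
the simulator, by construction, never violates it (this is property-tested).

Light events live in a `stimulus_log()`: millisecond timestamps, tube sets,
one of four colours (`off`, `white`, `blue`, `green`) and an intensity
fraction. Events must be time-sorted and per-tube deduplicated — a log is a
record of state *changes*. Traces use integer seconds and stimulus events
integer milliseconds: acquisition is second-resolution while LED control is
millisecond-precise, and the two never need a common clock finer than that.

Zeitgeber Time follows the usual convention: ZT0 = lights-on (8 a.m. under
the standard housing), dark phase ZT12–24 under 12:12 LD; `zt_at()` maps
elapsed session seconds onto the ZT circle given the ZT hour at session
start.

The CSV dialects are deliberately minimal (a handful of `#` header lines and
unquoted rows; see `?write_activity_csv`). One extension beyond the fixed
headers: an optional `#flies=` line carries fly identifiers so that
write→read round trips are lossless; readers fall back to `tubeNN` labels
when it is absent.

## Protocols and the closed-loop controller

`protocol_spec()` describes a session declaratively: a habituation period
(30 min of constant white light by default), then either

* a **sudden-darkness pulse train** — 1-s lights-off pulses at a fixed
  inter-trial interval (ITI). `darkness_protocol()` defaults to the 6-trial
  / 30-min-ITI / 3-h configuration; 2-h sessions at 5-min and 1-min ITI give
  24 and 120 pulses;
* a **12:12 light:dark cycle** for long-term recording; or
* a **feedback rule** for place preference.

`compile_protocol()` expands open-loop protocols deterministically into a
stimulus log. Feedback protocols are executed rather than compiled: every
second the controller reads each fly's beam position, assigns a zone (left
of the boundary beam / right of it), and lights the fly's whole tube in the
occupied zone's colour.

Controller conventions, each chosen for a reason:

* **Tick = 1 s.** Acquisition is per-second, so sub-second reaction is not
  modellable from the data.
* **Boundary beam 9 with hysteresis.** The midpoint of 17 beams is the only
  symmetric split; a fly sitting exactly on the boundary keeps its previous
  zone, which prevents LED chatter. A fly that starts on the boundary
  defaults to the left zone (and the controller says so).
* **One-tick latency.** The colour applied during second *t* is the rule
  colour of the zone occupied at *t − 1*, mirroring a real
  read→decide→write loop. This makes the contract testable: the acceptance
  suite brute-force rechecks every logged colour against the recorded
  positions.
* **Whole-tube colouring.** All LEDs of a tube take the occupied zone's
  colour (tubes are atomic illumination units; per-LED granularity is out of
  scope).
* **Zone swap** (`swap_at_s`) interchanges the colour *mapping*, not the
  accumulated zone labels.

## The generative fly model

`fly_params()` parameterises a deliberately minimal 1-D agent — the simplest
kinematics that produces realistic beam-crossing traces, since tube monitors
record nothing richer:

* Each second the fly moves with probability
  `clamp(p_move * phase_factor + effective_beta, 0, 1)`. Defaults:
  `p_move = 0.25`, `light_factor = 1`, `dark_factor = 0.5` (tube-confined
  flies are roughly half as active in the dark phase).
* A moving fly displaces by a zero-mean Gaussian (`step_scale = 4` mm, one
  beam spacing) plus drift, with reflecting walls.
* **Crossings** are the nearest-beam cell boundaries crossed along the
  (possibly folded) path, with a floor of one: a fly that moves at all
  interrupts at least its local beam. The floor makes the per-second
  movement indicator Bernoulli(`p_move`) exactly, and boundary counting
  guarantees the displacement invariant.
* **Startle.** A lights-off pulse raises the movement rate by an additive
  increment that decays exponentially (`startle_gain = 0.4`,
  `startle_tau = 12` s — the response has essentially faded within the 30-s
  analysis window). Negative gains model freezers; zero gains
  non-responders.
* **Habituation.** Each stimulus multiplies the effective gain by
  `habit_decay^n_eff`, where the load `n_eff` increments per stimulus and
  relaxes toward zero with time constant `habit_recovery` (600 s). This
  decay-with-recovery kernel — rather than a fixed per-trial decrement — is
  what makes desensitisation ITI-dependent: 1-min trains accumulate load
  almost fully (recovery factor `exp(-60/600) ≈ 0.90` between stimuli) while
  30-min trains recover almost completely. `effective_startle()` exposes the
  deterministic recursion, and the C++ engine is cross-checked against it.
* **Food attraction.** Drift toward the nearer tube end (weights per end),
  plus an extra dark-phase drift toward the ethanol end
  (`ethanol_dark_boost`) — the generative counterpart of a circadian
  ethanol preference. Food interaction is positional only; ingestion is not
  modelled, exactly as the assay infers it.
* **Blue-light aversion.** An innate drift out of the occupied zone while
  the tube is lit blue, and a *position-bound* learned component: each
  second of blue exposure adds `learn_rate` to an avoidance weight for the
  side where it was experienced, saturating at `learn_cap`. Binding the
  memory to the side (not the colour) is what makes the zone-swap assay
  collapse to chance: after the swap the fly re-learns the other side until
  both weights saturate and cancel. No forgetting term is included — the
  saturation alone reproduces the observed dynamics, and a forgetting rate
  would be unidentifiable from occupancy curves alone.

Cohorts (`make_cohort()`) draw each fly's responder class from a
`(none, negative, positive)` mixture. The line presets encode the observed
zero-delta rates (59% for the red-eyed wild type, 31% for the white-eyed
mutant, startle-free for the fragile-X model) and give the white-eyed line a
slower-recovering, deeper habituation kernel, matching its greater
sensitivity to repeated stimulation.

All randomness flows through R's global RNG: a session seed fixes
trajectories bit-exactly, and cohort draws take their own seed so cohort
composition is stable across protocols.

### What the simulator does and does not emulate

It emulates per-second count/position statistics, startle responses with
ITI-dependent desensitisation, LD activity modulation, end-dwelling with a
dark-phase ethanol bias, and innate/learned blue-light avoidance. It does
not emulate 2-D kinematics, jumps or wing responses, ingestion, sleep bouts,
inter-fly interaction, or trial-to-trial within-fly gain variability (a
per-trial random effect was considered and left out of the default model;
heterogeneity enters only between flies). Tests passing on simulated
cohorts therefore validate the *analysis pipeline and its calibration* —
they do not certify any biological claim about real flies.

## Analyses

**Delta index** (`delta_index()`): mean counts/s over the 30 s after a
stimulus minus the mean over the 30 s before, the stimulus second excluded —
pre window `[t-30, t)`, post `(t, t+30]`, second-aligned. The sign
convention (after − before) makes darkness-induced locomotion positive.
Stimuli closer than one window to a session edge are skipped with a
warning. Dead flies — zero counts in *every* pre and post window across the
session — are excluded by `exclude_dead()`; activity between windows does
not rescue a fly, because the rule as stated looks at the scored windows
only. `classify_responses()` partitions fly-by-trial cells by the exact sign
of the delta; "no change" is exact equality, not a tolerance band, which is
well-defined because window sums are integers (deltas are multiples of
1/30).

**Epoch averaging** (`epoch_average()`): trials are binned by stimulus time
into half-open 30-min epochs counted from the first stimulus, so a 2-h
session holds 4 epochs of 6 (5-min ITI) or 30 (1-min ITI) deltas per fly.
Empty epochs are reported as `NA` and flagged, never silently dropped.

**Baseline metrics** (`baseline_metrics()`): mean counts/s and mean speed
over the 20 min before the first stimulus. Speed is defined as mean absolute
per-second beam displacement (beam cells/s) — the only speed computable from
the stored channels.

**Preference** (`end_occupancy()`, `zone_occupancy()`,
`zt_correlation()`): positional dwell, not counts — "time spent" is a
position statement. The food assay scores each side's last two beams and by
default starts at the first ZT0 of the recording (letting placement effects
wash out); the offset is a parameter. The ZT correlation pools fly-by-bin
points (per-fly averaging is available as an option) and flags, rather than
computes, zero-variance series.

**Statistics** (`pearson()`, `anova_oneway()`, `linear_trend()`): the trend
test is the orthogonal linear contrast over ordered epoch means — centred
scores as coefficients, contrast mean square against the within-group mean
square on (1, N − k) degrees of freedom. The reported slope is per epoch,
and `R2` is the contrast share of the *between-group* SS (the convention of
the common post-test-for-trend implementations), not of the total SS. Both
conventions matter when comparing printed slopes and R² values across
tools. Two-way and repeated-measures ANOVA and post hoc family corrections
are deliberately out of scope; the exported per-fly tables support any
external stats backend.

## Numerical conventions and degenerate inputs

* Window arithmetic is second-aligned and half-open throughout; the
  stimulus second belongs to neither window.
* Zero-variance inputs: `pearson()` refuses; `zt_correlation()` flags.
* Flat group means give trend `R2 = 0` by convention (the contrast share of
  a zero between-SS is taken as 0, slope 0).
* Degenerate groups (n < 2) are errors, not silent drops.
* Reflecting walls fold the displacement path; crossings accumulate over
  the folded segments, so wall contact never loses counts.
* File round trips are bit-identical: timestamps are whole seconds,
  floating headers use 17 significant digits.

## Problem sizes used in the checks

The calibration and power checks run at the assay's own design points:
null calibration with 200 replicate cohorts of 58 zero-gain flies under the
6-trial darkness protocol; gain recovery over a 3-point gain grid at 100
replicates against an independent Monte-Carlo oracle; habituation power
with 200 replicates of 96 flies under the 1-min-ITI 2-h protocol (with a
`habit_decay = 1` arm to confirm nominal false-positive rates); ethanol
preference with 15 flies over 48 h; place preference with 32 flies over 5-h
(and 10-h swap) sessions. Monte-Carlo rejection rates are judged against
central binomial bands at the replicate count used.
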