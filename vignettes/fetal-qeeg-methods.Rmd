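---
title: "Quantitative EEG analysis of fetal hypoxia under repeated cord occlusions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG analysis of fetal hypoxia under repeated cord occlusions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetalqeeg)
```

## The problem this package addresses

During labour, umbilical cord compressions expose the fetus to repeated
short episodes of total hypoxia. The fetal brain responds in two distinct
ways: an immediate, per-occlusion suppression of electrocortical activity
(thought to be an energy-sparing, possibly neuroprotective adaptation),
and a progressive background deterioration — slowing and amplitude loss —
once cardiovascular compensation begins to fail. Quantitative EEG (qEEG)
features can separate these two signatures and relate them to the
haemodynamic and gasometric state of the fetus.

`fetalqeeg` implements that analysis end to end for the near-term fetal
sheep preparation in which it was developed: a stability hour followed by
three one-hour phases of 1-min total cord occlusions repeated every 5 min
(phase A, mild), 3 min (phase B, moderate) and 2 min (phase C, severe),
with a 5-min occlusion-free pause every 20 min and a hard stop once
arterial pH falls below 6.90. Because no public recording of such an
experiment exists, the package ships a synthetic generator that produces
cohorts with the statistical structure the analysis assumes; real
recordings, when available, enter through the same EDF and delimited-text
interfaces.

## The protocol model

`protocol_config()` / `build_protocol()` expand the protocol into a
contiguous event table (stability, occlusion, inter-occlusion, pause).
The published description fixes the occlusion period per phase and states
that a 5-min pause is observed every 20 min, but not how occlusion cycles
and pauses interleave within the hour. We adopt the convention that each
hour consists of three 20-min blocks, each being 15 min of occlusion
cycles followed by one 5-min pause; occlusion onsets are placed every
period from the block start for as long as a *full onset-to-onset cycle*
fits into the 15-min span. This satisfies both stated rules, yields 9, 15
and 21 occlusions in phases A, B and C, and is surfaced entirely through
configuration so alternative layouts remain expressible. No occlusion ever
overlaps a pause.

The stop rule (`apply_stop_rule()`) truncates the schedule at the first
gasometry sample whose pH falls below the threshold. Blood gases are
*measured* only at the stability draw and at the last pause of each phase
(the experimental sampling scheme), but the simulator maintains a dense
latent trajectory between the configured per-phase targets;
`simulate_subject()` checks that latent trajectory against the threshold
so a crossing can stop the protocol mid-phase, the way continuous
clinical surveillance would.

## The synthetic generator

### EEG

Each of the four monopolar channels (left/right frontal and parietal,
256 Hz) is coloured Gaussian noise shaped in the frequency domain by a
band-power profile (defaults concentrated in the delta/theta range so the
stability spectral edge sits near 8–10 Hz, within the range observed in
near-term fetal sheep). Per phase, the band edges are multiplied by a
slowing factor (1 / 0.95 / 0.85 / 0.75 for S/A/B/C) and the amplitude by
a scale (1 / 0.95 / 0.8 / 0.7), emulating progressive background
slowing and amplitude loss. A slow sinusoidal amplitude modulation
(25% depth, 60-s period, random phase) stands in for the lability of the
normal trace.

During each occlusion the amplitude gain ramps down (1-s ramp, after a
5-s latency) to the phase's *retained fraction* — 0.8 / 0.5 / 0.1 for
mild/moderate/severe by default, so severe occlusions are near-isoelectric
— and recovers at release. Damped ~1-Hz high-amplitude wavelets may
accompany onset and release (probability 0.5), mimicking the transient
large waves seen at occlusion boundaries. A small white instrumentation
floor (0.1 µV RMS) is never suppressed; at that level its out-of-band
power share is ~1e-4, so the recording remains band-limited to 0.5–70 Hz
for practical purposes.

Every stochastic component draws from a named substream of the subject
seed (channel × phase, transients, floor, …), so identical
`(schedule, config, seed)` give bit-identical signals and adding one
component never perturbs another's stream.

### Physiology

Heart rate and mean blood pressure are 1-Hz series: HR at baseline
(186 bpm) dropping to the phase's occlusion level (85/80/79 bpm) during
every occlusion from the very first one; MBP at baseline (48 mmHg)
rising between occlusions by a per-phase delta (to 58/62/64 mmHg) and
taking the per-phase occlusion value (56/54/37 mmHg — hypotension only in
the severe phase). Gasometry interpolates per-phase targets
(pH 7.39 → 7.28 → 7.10 → 6.98; pCO2 45 → 65 mmHg; lactate 2.3 → 16
mmol/L; pO2 essentially stable) and is sampled with small measurement
noise at the experimental sampling times. These levels are the observed
cohort phase medians of the source preparation; they are conditions of
the simulation, not quantities the pipeline is expected to rediscover.

The physiology is phenomenological by design — no ODE cardiovascular
model — because the analysis only consumes windowed medians and rank
statistics. The phase ladder itself couples EEG suppression to
bradycardia and (in the severe phase) hypotension, which is what gives
the correlation grid its expected signs.

### Cohorts

`simulate_cohort()` applies per-subject multiplicative jitter (log-normal
on amplitude, HR, MBP and gas targets; additive on pH; logit-scale on the
retained fraction) from seeded substreams, giving reproducible
inter-individual variability. Per-subject fields can be overridden, e.g.
to give one subject a gas trajectory that breaches the stop rule — the
configuration used throughout the analysis scripts to reproduce a cohort
that loses its ninth subject before the severe phase (n = 8 in phase-C
cells).

### What the generator does *not* emulate

Sleep-state cycling, movement and maternal artefacts, electrode drift,
ECG cross-talk, and genuinely discontinuous (burst-suppression-patterned)
background. Tests passing on this generator therefore demonstrate the
correctness of the *pipeline* — window logic, feature definitions,
statistics — and the recoverability of planted effects, not robustness to
real-world artefact.

## The qEEG features

All three features are computed on non-overlapping 2-s intervals, aligned
to the recording start, on the two bipolar derivations (left−right
frontal, left−right parietal), then averaged across the two derivations.
Channel averaging precedes windowed median-taking.

**minAI** — the minimum of the amplitude envelope over the interval. The
envelope (CFM/aEEG style) is: zero-phase 2–20 Hz Butterworth band-pass →
rectification → sliding 125-ms maximum → 0.5-s moving average. The
commercial analyser's algorithm is unpublished; this construction
reproduces aEEG-style envelopes, converges to the peak amplitude of a
constant sine, and is fully testable.

**BSR** — the percentage of the interval covered by suppression, where a
suppression is a maximal run of envelope strictly below 10 µV lasting
strictly longer than 500 ms. The amplitude criterion is evaluated on the
envelope, not on raw samples (a raw oscillation crosses any threshold
every half-cycle, which would make the rule degenerate). Runs are found
on the continuous timeline and intersected with intervals, so a
suppression spanning an interval edge is never lost. Envelope smoothing
smears each suppression boundary by a fixed few hundred milliseconds;
planted suppression fractions are recovered within 5 percentage points
over windows long relative to that smear, and the run detector agrees
*exactly* with a sample-wise scanner because both operate on the same
envelope.

**SEF** — the smallest frequency below which 95% of the interval's
0.5–70 Hz power lies, from a periodogram of the 2-s interval (0.5-Hz
resolution). The periodogram taper is configurable; the default is
rectangular rather than Hann because at this resolution a rectangular
window makes bin-aligned line spectra exact (a pure 8-Hz tone reads
8.0 Hz, equal-power 4 + 16 Hz tones read 16.0 Hz) while broadband SEF
estimates differ negligibly. When total in-band power falls below a
floor — the expected periodogram power of a 1-µV-RMS white signal,
configurable — the SEF is reported as *undefined* (`NA`) and excluded
from medians. This is a deliberate design point: commercial monitors
that return a fixed high frequency on isoelectric signal produce
artefactual "fast" readings during suppression, and the pipeline must
never do that.

## Windows, summaries, tables

Per subject, every marker is summarised over: the stability hour; each
whole phase (including occlusion intervals — the reported rise in
whole-phase BSR with occlusion frequency indicates the source analysis
did the same); the last *completed* occlusion of each phase (1 min); and
the last *completed* pause (5 min). Under stop-rule truncation "last"
means last completed before the stop; a phase with no completed occlusion
contributes no per-occlusion window. Undefined SEF intervals are excluded;
a window with no defined values yields a missing marker, never a number.

Quartiles use linear interpolation between order statistics (type 7); the
convention is configurable because Q1/Q3 of n = 9 differ across
conventions and the source does not state one. Cohort cells are the
across-subject median (Q1; Q3) of per-subject medians ("median of
medians"), with per-cell n recorded, so a subject lost to the stop rule
visibly reduces n in the affected phases.

## The statistical stage

Friedman's repeated-measures test compares each marker across phases
(S/A/B/C for whole-phase and pause markers, A/B/C for per-occlusion
markers), on complete-case subjects with `n_used` reported — a subject
stopped before phase C cannot contribute a complete row. Where Friedman
is significant at α = 0.05, pairwise Wilcoxon signed-rank post-hoc tests
are run with zero differences dropped, the exact null for up to 15
remaining pairs (the exact path requires tie-free absolute differences;
with ties the mid-rank normal approximation is used and labelled), and
no multiple-testing correction — matching the source analysis; Holm
correction is available behind a flag. Spearman correlations between the
six qEEG and eight physiological markers pool subject × occlusion-phase
observations (27 for a full cohort of 9, fewer under truncation), the
pairing consistent with the source's reported degrees of freedom. The
test engines are R's `friedman.test`, `wilcox.test` and `cor.test`;
independent brute-force ranking/enumeration oracles in the test suite
verify the statistics they produce.

### Calibration at desk scale

Type-I calibration (rejection rate under no phase effect) and power under
the severity ladder are assessed with a *summary-level* generator
(`simulate_summary_grid()`): per-subject phase values drawn as subject
offset + phase mean + noise, with parameters estimated from the wSEF grid
the full pipeline actually produced (`calibrate_summary_generator()`,
a two-way additive variance decomposition). Re-simulating raw EEG for
every one of 1200 replicate cohorts would add nothing to what is being
tested — the behaviour of the rank statistics at n = 9 — so replicates
are generated at the level the tests consume: 1000 null cohorts for the
size check (observed rejection ≈ 5% at α = 0.05) and 200 ladder cohorts
for power. One full-pipeline cohort of nine subjects under the complete
four-hour protocol anchors those parameters and all qualitative checks.

## Numerical and degenerate-input choices

* Band-pass: 4th-order Butterworth, forward-backward (`filtfilt`), zero
  phase, stop-band attenuation far beyond 40 dB one octave out.
* Strict inequalities in the suppression rule (`< 10 µV`, `> 500 ms`),
  matching the stated criteria; a run of exactly 500 ms does not count.
* Intervals shorter than 2 s, empty summary windows, all-zero difference
  vectors, zero rank variance: each returns a typed error or an explicit
  flag (`degenerate`, `undefined`), never a silent number.
* EDF export clips (never wraps) at the ±1000 µV physical range; the
  quantisation step is 2 × 1000 / 2^16 ≈ 0.03 µV.
* Seeds: one master seed; every component draws from a named substream
  (hash folded into 31 bits with arithmetic exact in doubles).

## Problem sizes

The shipped analysis and acceptance runs use: one 4-h cohort of nine
subjects at full resolution (14 400 s × 4 channels × 256 Hz per subject;
7 200 analysis intervals per derivation), 1000 random envelopes for the
suppression-oracle agreement check, and 1000 + 200 summary-level cohorts
for the statistical calibration. Unit tests run the same code on a
structurally identical shortened protocol (240-s stability, 720-s phases,
60-s pauses) chosen as the smallest layout that still exercises blocks,
pauses and truncation.

## Known limitations

* The envelope algorithm and the vendor SEF band are stand-ins for
  unpublished commercial definitions; both are configurable.
* The generator's physiology is phenomenological; correlations arise from
  the phase ladder, not from a mechanistic cardiovascular model, so
  effect *sizes* in the correlation grid are not comparable to animal
  data — only directions are.
* Whole-phase medians include occlusion intervals; if the source analysis
  excluded them, whole-phase BSR levels would differ (directions are
  unaffected).
* No artefact rejection: real recordings must be artefact-screened before
  entering the pipeline.
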