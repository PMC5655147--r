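---
title: "Quantifying ripple-spindle coupling in dual-site LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ripple-spindle coupling in dual-site LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During NREM sleep, hippocampal CA1 emits sharp-wave ripples (brief
100-250 Hz bursts) while neocortex emits sleep spindles (12-15 Hz
waxing-waning oscillations, 0.2-2 s) and delta waves (1-4 Hz). Their
above-chance temporal co-occurrence — ripple-spindle coupling — is read
as a signature of hippocampo-cortical dialogue during memory
consolidation, and experimental manipulations are often evaluated by
whether they strengthen or abolish it. `lfpcoupling` implements the full
per-session measurement chain for dual-site recordings (one CA1 LFP, one
ACC LFP, one EMG channel, nominally digitized at 2 kHz): sleep staging,
oscillatory event detection, band-power summaries, and three coupling
statistics with a shuffle-based significance test. Group-level inference
across animals is out of scope; the pipeline emits per-session metrics.

Because public datasets with this exact channel configuration are not
bundled, the package ships a synthetic session generator
(`generate_recording()`) with full ground truth, and every stage is
validated against it.

## Sleep staging

Staging uses two adaptive thresholds, both defined as multiples of a
histogram mode (`estimate_mode()`, Freedman-Diaconis binning, ties to the
lower bin). The mode tracks the dominant baseline level and ignores the
heavy right tail contributed by movement and oscillatory events, which is
why it is preferred over the mean here.

1. **Immobility.** The EMG Hilbert envelope, smoothed with a 0.5 s moving
   average, is compared with `3 x mode`; maximal sub-threshold runs of at
   least 10 s are immobile. Both the envelope and its mode scale with any
   channel gain, so immobility is gain-invariant. A consequence of the
   self-referential threshold worth knowing: a recording whose EMG is
   *uniformly* quiet (or uniformly loud) is entirely "immobile", because
   the mode adapts to the only level present. Wake is recognized by EMG
   *burstiness* — movement bursts a few seconds apart keep every
   sub-threshold run below the 10 s minimum.
2. **NREM vs REM.** Immobile time is tiled into 2 s epochs (matching the
   2 s spectral bins used throughout; boundary epochs are truncated,
   slivers under 1 s dropped). Per epoch, the theta (4-12 Hz) to delta
   (1-4 Hz) power ratio is computed from a Welch PSD of the CA1 LFP
   (configurable; CA1 is the stronger theta source). Epochs below
   `3.5 x mode` of the session's ratio distribution are NREM, above it
   REM. The threshold is re-estimated per session ("adaptive" read as
   per-session, not sliding-window). With fewer than 100 immobile epochs
   the mode estimate is unreliable and the median is used instead.

At the recording lengths this pipeline targets, sustained REM is rare;
the scorer still labels REM and reports its total so downstream checks
can assert it stays small.

## Event detection

All three detectors share one rule (`detect_threshold_events()`): take
the Hilbert envelope of the band-passed channel, compute a baseline mean
and SD over NREM samples, threshold at `mean + k x SD`, merge
supra-threshold runs closer than the merge gap, then apply duration
bounds. Presets: ripples (CA1, 100-250 Hz, k = 3, merge 50 ms, no
duration bounds), spindles (ACC, 12-15 Hz, k = 2, 200-2000 ms, merge
100 ms), delta waves (ACC, 1-4 Hz, k = 1.5, 150-500 ms, merge 100 ms).

Decisions the criteria leave open, and how they were fixed:

* **Threshold semantics.** "k times the SD" is implemented as
  `mean + k x SD` of the envelope, because an envelope is strictly
  positive: a bare `k x SD` cut can fall *below* the envelope mean and
  select most of the trace. The bare rule is available as
  `threshold_rule = "k_sd"`.
* **Baseline scope.** Mean/SD come from NREM samples only (the events
  are defined within NREM); whole-recording scope is available by
  configuration.
* **Operation order.** Merge before duration filtering: a brief envelope
  dip inside one long spindle would otherwise fragment it into two short
  pieces that the minimum-duration rule then rejects. A regression test
  pins this order.
* **Boundaries.** Candidates straddling an NREM edge are clipped to it,
  then duration-filtered.
* An optional minimum duration for ripples (off by default, matching the
  criteria, which state none) is exposed for noisy data.

Filtering is a 4th-order Butterworth applied forward-backward
(`signal::filtfilt`), i.e. zero phase — mandatory here because event
timing feeds the lag statistics; any phase delay would bias every
correlogram peak. The Hilbert envelope is the modulus of the FFT-derived
analytic signal.

### What detection can and cannot achieve on the synthetic floor

The generator's background is spectrally shaped *Gaussian* noise, so a
band-limited envelope is Rayleigh-distributed. An adaptive
`mean + 3 SD` threshold is then crossed by background alone roughly once
per ~170 envelope decorrelation times, independent of scale — for the
150 Hz-wide ripple band that is on the order of one crossing per second
of NREM. These crossings are real properties of the rule, not bugs: at a
realistic event-to-background ratio (`event_snr = 5`, where implanted
peaks sit barely above the `mean + 3 SD` line at ~4.9 background-SD
units) ripple detection on this noise floor has high recall but low
precision, and spindle detection is marginal in both directions (the
2 SD threshold sits at ~0.6 of the event envelope peak, so detected
durations under-cover the implanted 700 ms). On real LFP — whose
envelope distribution is far heavier-tailed, with the SD inflated by
genuine events — the same rule behaves much more selectively. Tests that
depend on detector output therefore assert the levels the rule actually
attains on this floor, and the coupling analyses anchor on ground-truth
event times where detector confounds would obscure the quantity under
test.

## Spectral summaries

`welch_psd()` averages Hann-tapered periodograms of 2 s segments at 50%
overlap (density scaling). Band fractions use five canonical bands
(delta 1-4, theta 4-12, alpha 12-20, beta 20-40, gamma 40-100 Hz) with
half-open binning `[low, high)` so shared edges are counted once and the
fractions sum to exactly 1; the denominator is total 1-100 Hz power
(whether power above 100 Hz belongs in the denominator is unspecified in
the source criteria; fixing it to 1-100 Hz makes the five fractions a
partition).

## Coupling statistics

**Amplitude cross-correlogram** (`amplitude_xcorr()`). For each anchor
(spindle centre, or delta onset for the ripple-delta variant), the
anchor-band envelope over `[c-W, c+W]` is Pearson-correlated with the
ripple envelope over `[c-W+tau, c+W+tau]` on a lag grid (`W = 4` s, lags
every 0.01 s; `W = 0.5` s for delta onsets), restricted to NREM;
coefficients are averaged across anchors. Negative peak lag = ripple
leads. The per-anchor-window formulation (rather than one global
cross-covariance) matches the definition of a coefficient per
spindle-ripple pair averaged across spindle windows. NREM segments are
concatenated with their seams recorded; anchors whose most-shifted
window would cross a seam are dropped rather than zero-padded. Envelopes
are block-averaged down to the 0.01 s lag resolution before correlation
(an anti-alias average; the envelope carries no information above 50 Hz
that the lag grid could represent). Peak ties break toward the smallest
absolute lag. The implementation precomputes each anchor's sliding
cross-products once (FFT) and evaluates any lag/shift combination by
indexing; it is tested to 1e-10 against a naive per-lag Pearson loop.

**Shuffle null** (`shuffle_null_test()`). The observed peak is compared
with 100 recomputations in which the ripple envelope is displaced by a
random 4-10 s shift (sign equiprobable). Significance = observed peak
strictly above the nearest-rank 99th percentile (the largest of the
lowest 99 of 100). Whether the source procedure shifts each window
independently or the whole trace is ambiguous; both are implemented.
The default shifts the whole concatenated-NREM trace
(`mode = "global"`): this is the textbook circular-shift surrogate — it
preserves the ripple envelope's autocorrelation and the correlation
between overlapping anchor windows, and on 100 seeded null sessions its
false-positive rate stayed at its nominal level. The per-window variant
(`mode = "per_window"`, each anchor's ripple window shifted
independently) breaks the correlation between neighbouring anchor
windows that the observed statistic retains, so its null peaks are
drawn from a narrower distribution and the test becomes measurably
anti-conservative (~9/100 false positives on the same sessions). The
global null pays for its validity with power: because shifts of 4-10 s
overlap the typical spacing between spindles, shuffled windows land on
*other* spindles' genuinely coupled ripples, inflating the null peaks
on strongly coupled sessions and costing sensitivity at small anchor
counts. Note also the procedure's nominal level is 2/101 ~ 2%, not 1%:
exceeding the 99th of 100 exchangeable peaks happens when the observed
value ranks in the top 2 of 101.

**Timestamp cross-correlogram** (`timestamp_xcorr()`). Event centres are
binarized on a 0.1 s grid over concatenated NREM and the two 0/1 trains
are Pearson-correlated at integer-bin lags over +/-4 s (the coefficient
normalization for this method is not pinned by the source criteria;
Pearson on the binned trains was chosen and documented). Same sign
convention.

**Joint occurrence rate** (`joint_occurrence_rate()`). Ripples whose
centre lies within +/-0.25 s of at least one spindle centre (each ripple
counted once), divided by the spindle count. Tested for exact equality
against an O(n^2) enumeration.

**Pre-normalization** (`normalize_to_baseline()`, `compare_sessions()`).
Post-session coupling divided by the pre-session baseline, per measure.

### Lag estimation accuracy

The correlogram's coupled component is a dome whose width is set by the
*anchor* envelope (a ~700 ms spindle), not by the narrow ripple burst:
sliding the ripple bump across the spindle dome changes the coefficient
slowly near the top. Peak-lag precision is therefore limited by dome
curvature against averaging noise and improves only with the number of
anchor windows. At ~50 anchors (a 10-minute NREM session) the recovered
lag scatters by several tens of milliseconds around the implanted value;
recovering a -0.07 s lag to within one 0.01 s lag step requires
session lengths at the scale of the two-hour recordings the defaults
emulate (hundreds of anchors), and even there it is at the edge of what
the estimator resolves. The acceptance suite measures this honestly
rather than smoothing the correlogram, which would trade bias for
variance outside the defined method.

## The synthetic generator

`generate_recording()` builds three channels on a ground-truth
hypnogram (fixed-block by default: WAKE 60 s / NREM 240 s / REM 20 s
cycles; alternatively semi-Markov with exponential block lengths):

* LFP backgrounds are 1/f (exponent 1 by default) spectrally shaped
  Gaussian noise, normalized so the 100-250 Hz envelope SD is one unit,
  making `event_snr` directly interpretable.
* Implanted events: 80 ms Gaussian-windowed 150 Hz bursts (CA1 ripples),
  700 ms Hann-windowed 13 Hz bursts (ACC spindles), 250 ms half-wave
  deflections (ACC delta, with an attenuated copy leaked into CA1).
  Template amplitudes are calibrated so the band-passed envelope peak of
  the template equals `event_snr` background-envelope SDs in that band
  (the background then adds in quadrature, ~ +2% at snr 5; calibration
  SDs are estimated on a 60 s background prefix, standard error < 1%).
* Event times are Poisson in `rate x NREM seconds` (defaults: ripples
  0.15 /s, spindles 0.08 /s, delta 0.2 /s of NREM — conventional rodent
  values chosen as generator assumptions, not measurements), placed
  uniformly over NREM with margins and a minimum same-type separation so
  implanted events cannot merge. With probability `p_couple` a ripple is
  instead placed at a spindle centre plus `couple_lag_s` (default
  -0.07 s, ripple leading) plus Gaussian jitter (default SD 0.02 s, a
  realistic spread); at most one ripple per spindle by default, which
  keeps the ground-truth joint rate analytic.
* REM adds a 7 Hz theta component scaled to dominate the delta band;
  EMG is broadband noise at `emg_wake_gain` (10) during WAKE and
  `emg_sleep_gain` (1) otherwise, with 0.5 s ramps.
* Independent seeded sub-streams drive states, each channel's noise and
  the event times, so changing one leaves the others fixed.

What it does *not* emulate: non-Gaussian, heavy-tailed real LFP noise
(see the detection caveat above), spindle-slow-oscillation nesting, CA1
laminar structure, movement artifacts, electrode drift. Passing tests on
this generator show the *pipeline* is correct, not that detection
thresholds are optimal for any particular real dataset.

## Problem sizes used in tests

The test and acceptance suites run reduced problem sizes chosen as
sensible validation scales: 11-minute sessions with 10 minutes of NREM
at 1 kHz for the Monte-Carlo calibration/power studies (100 seeded
sessions each), a 30-minute 2 kHz session for detector recovery, and a
~90-minute-NREM 1 kHz session for lag recovery (where anchor count is
the limiting factor). The full pipeline report is byte-reproducible
under a fixed seed and configuration.

## I/O

Recordings move as raw little-endian float binaries with a JSON sidecar
(`fs`, roles, sample count, dtype — float64 round-trips losslessly) or
as plain EDF (16-bit, one 1 s record per second; exact to the physical
range divided by 2^16). Event tables and hypnograms are plain CSV with
`#`-prefixed metadata lines; session reports are deterministic JSON
validated against a shipped field schema.
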