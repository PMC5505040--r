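---
title: "Decoding movement intent from sEMG and inertial measurements: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement intent from sEMG and inertial measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgimu)
```

## The decoding problem

Upper-limb myoelectric control maps muscle activity to prosthetic hand
commands. Surface EMG alone degrades badly when the number of gestures
grows or the arm changes posture (the limb-position effect). Modern
wireless electrodes embed a 9-axis IMU in the same pod as the EMG
amplifier, so each sensor contributes 10 raw signals — one sEMG channel
at 2 kHz and accelerometer/gyroscope/magnetometer triads at 128 Hz — and
the postural information in the inertial channels can be fused with the
myoelectric information at the feature level. `emgimu` implements that
fusion pipeline end to end, together with the analyses that motivate it:
how much each modality contributes, how few sensors suffice, and how much
of the EMG envelope the inertial channels can linearly explain.

## Signal model and synthetic data

The generator is the package's stated world; every green test should be
read relative to it.

* **EMG** is amplitude-modulated Gaussian noise: during a class-`c`
  segment, sensor `s` emits zero-mean noise with standard deviation
  `emg_gain[c+1, s] * noise_sd_emg`. This is the standard surrogate for
  interference-pattern EMG: all features used downstream (MAV, WL, AR,
  LogVar) depend only on second-order statistics, so a motor-unit-level
  simulation would add realism the decoders cannot see.
* **IMU channels** carry class structure in their means
  (`im_offset[c+1, j]`), emulating postural offsets; the decoders use
  only window means of these channels. Optional linear coupling injects
  the per-sensor EMG amplitude envelope into chosen IMU channels for the
  reconstruction analyses.
* **Protocol structure** follows the acquisition sessions: a leading
  rest, then for each class `n_repetitions` trials interleaved with
  rests (defaults 5 s + 5 s, 40 classes × 6 repetitions offline; 5 grips
  + rest, 5 repetitions for the real-time protocol). Rest is a genuine
  class (row 1 of the gain/offset matrices), as in the experiments.
* **Imperfections** available on demand: 50 Hz powerline interference
  (`powerline_amp`), label-onset jitter relative to the true signal
  transitions (`onset_jitter_ms`), and uninformative sensors
  (class-independent rows) for planted-truth selection tests.

What the generator does **not** emulate: electrode shift, fatigue,
within-class postural variability beyond the per-class offsets,
crosstalk, or real EMG spectra. A green pipeline test therefore
establishes correctness of the computation, not field performance on
human recordings; the headline accuracies printed by the tests are
properties of the planted world.

Where neither protocol nor physics fixes a value we chose once:
`noise_sd_emg = 1` (arbitrary units; gains are relative),
`noise_sd_im = 0.2` with class offsets of order 1 (window means over
hundreds of samples make these trivially separable, which is what a
"strong separation" acceptance world requires), and deterministic default
gain/offset patterns so that the stated world does not drift with the
seed.

## Preprocessing

**Hampel filter.** Powerline transients are suppressed by a sliding
median test: sample `i` is replaced by its window median when
`|x_i − med_i| > n_sigmas · 1.4826 · MAD_i` (half-window 100 samples,
`n_sigmas = 3`). The inequality is strict, which settles both degenerate
cases at once: flat segments (deviation 0, threshold ≥ 0) are never
rewritten, while a lone impulse in an otherwise constant window
(deviation > 0, MAD = 0) is removed. Edge windows are truncated
symmetrically. The exact filter variant used upstream of the original
recordings is not recoverable; this time-domain sliding variant is the
package's normative, documented surrogate. Note that the filter is only
*nearly* idempotent: removing a spike shrinks neighbouring window MADs,
so a second pass can flag a handful of borderline samples (the suite
bounds this at <1%).

**Synchronisation.** IMU channels are linearly interpolated from the
128 Hz grid onto the 2 kHz EMG grid so both modalities share exact window
boundaries. Outside the IMU time span the nearest sample is held
constant — never linear extrapolation, which can diverge. Interpolated
values at original IMU sample times reproduce the originals exactly.

**Label refinement.** Cue-following delays misalign protocol labels with
true muscle activity. The refiner moves each labelled onset/offset within
±`search_ms` to where the multi-channel smoothed EMG power (moving
average of the mean squared sample over `smooth_ms`) crosses the midpoint
between neighbouring rest and active levels. Search windows are clipped
at adjacent movement segments, and only boundary times move — class
sequence and segment count are invariant. This is a declared surrogate
for the original study's relabelling procedure, whose exact algorithm is
likewise not recoverable.

## Features

Windows are 256 ms long and shift by 50 ms (80% overlap), the standard
compromise between accuracy and controller delay; the label of a mixed
window is the majority label, ties resolved toward the window end
(the later class), a rule the protocol leaves open. Per sensor and
window:

* `MAV = mean(|x|)`, `WL = Σ|x_{i+1} − x_i|` — amplitude and complexity;
* AR(4) coefficients of `x_t = Σ_j a_j x_{t−j} + e_t`, estimated by the
  Burg method (stable on short windows; lattice recursion vectorised
  across windows, verified against `stats::ar.burg` to 1e-10). The
  forward-prediction sign convention is fixed normatively since field
  usage varies;
* `LogVar = log(s²)` with the unbiased variance floored at `1e-12`, so a
  constant window maps to `log(1e-12)` rather than `-Inf`;
* the 9 IMU window means, computed on the synchronised 2 kHz grid so both
  modalities share window boundaries exactly (for 256 ms means the
  difference from the native grid is negligible).

That is 16 features/sensor: 84 (EMG), 108 (IM) or 192 (both) columns for
12 sensors, in contiguous per-sensor blocks so selection can operate on
sensors as groups. Standardization (centre, unit variance) is always
fitted on training rows only; zero-variance columns are dropped with a
warning.

The repetition index of each window — the ordinal of its enclosing
movement segment within its class — is carried through the matrix; rest
windows inherit the repetition of the neighbouring segment so that
repetition-wise folds partition *all* windows.

## Classifier

LDA as a class-conditional Gaussian model: per-class means, empirical
priors, and a pooled within-class covariance shared across classes, which
makes the decision boundaries linear and, crucially for control, yields
calibrated posteriors `p(c|x)`. Two numerical choices matter at `d = 192`
with desk-scale training sets:

* **Shrinkage.** The pooled covariance is shrunk toward its diagonal,
  `(1−λ)Σ + λ diag(Σ)`, default `λ = 1e-3` — enough to guarantee a
  Cholesky factorisation without measurably moving the boundaries. At
  `λ = 1` the model reduces to shared-variance naive Bayes (tested
  against an independent implementation).
* **Log-domain densities.** All densities are evaluated through the
  Cholesky factor in the log domain and normalised by the row maximum, so
  posteriors neither overflow nor underflow anywhere in float range.

Rejection: a prediction is emitted only when the winning posterior
strictly exceeds `θ` (default 0.995, set a priori for real-time control);
otherwise the result is `NO_DECISION`, a first-class value the controller
consumes as "hold state". Raising `θ` provably never grows the emitted
set.

## Evaluation

Folds are repetitions: fold `j` holds out repetition `j` of every class
(repetition `r` maps to fold `((r−1) mod k)+1`, keeping the partition
exhaustive if extra repetitions exist). Because rest dominates the window
counts, test folds are balanced: rest windows are ranked by temporal
distance to the nearest movement window and the nearest (hardest) are
kept until rest matches the rounded mean movement-class count. The
protocol description fixes only that "a large proportion" of rest is
removed by temporal distance; equalising to the mean count is the
least-arbitrary reading and is configurable. Distances are measured
between window times within the fold — identical to segment-boundary
distance up to one window increment and well-defined on the feature
matrix alone. `CA = 100 · correct/total` per fold; confusion counts are
pooled across folds then row-normalised. Bootstrap CIs are percentile
intervals of the mean (100 iterations, seeded).

## Sensor selection

SFSS ranks sensors greedily: each candidate is scored by adding its full
feature block and computing per-fold CA; each fold votes for its best
candidate, majority wins (vote ties → higher mean CA, then lower sensor
index — the tie rule is ours, the protocol states none). The stopping
rule is a prefix: keep adding while the marginal mean-CA gain exceeds 1
percentage point, stop at the first failure (the first sensor is always
kept). The non-contiguous reading ("keep any sensor whose gain exceeds
1%") is deliberately not the default: the prefix rule is deterministic
and matches how selection curves are read in practice. Selection on
training data defaults to 3-fold CV, an assumption documented here since
the original protocol does not state the fold count for selection.

A caution that shaped the test design: with one overwhelmingly
informative sensor, every later gain ties at zero and the ranking's tail
is decided by the tie rule alone. Planted-truth recovery is therefore
tested with two *complementary* informative sensors (one resolves class
parity, one the class pair), where top-2 recovery is the unique correct
outcome rather than a tie-break accident.

## Control simulation

The finite-state controller has two states. While `EXECUTING` (a fixed
`exec_duration_s = 1` surrogate for the hand's motor-current termination
sensing, which a simulator cannot reproduce) all predictions are ignored.
While `IDLE`, a command fires iff the winning posterior exceeds `θ`, the
class is a movement (rest never fires), and it differs from the current
pose (re-gripping a formed grip is a physical no-op; suppression is a
declared simulator choice). Decisions tick at the 50 ms window cadence.

A pick-and-place trial requires the 7-command sequence (three grips, each
followed by open, then the index-pointer press) within the time limit
(60 s able-bodied, 75 s amputee). The human correction loop is encoded as
a scoring rule: a wrong command invalidates progress until an open
command is issued. CR is the percentage of successful trials; CT
statistics are computed over successes only, with no CI below two
successes.

## Envelope reconstruction

For each sensor and each inertial modality, ordinary least squares with
intercept maps the modality's three window-mean axes to the same sensor's
MAV series; the score is `VAF = 1 − var(residual)/var(envelope)`,
reported in-sample and cross-validated (held-out is the headline number,
the conservative choice where the original analysis does not state
which). For a single coupled channel `z = c·e + ε` the expected VAF is
`c²var(e) / (c²var(e) + var(ε))`, which the suite uses as a closed-form
oracle at VAF = 0.5. VAF is invariant to affine rescaling of the
predictors. The 25–30% figures reported on human recordings are
properties of those recordings, not of this generator, and are
deliberately not acceptance targets; the planted-coupling recovery is.

## Budgets and scale-downs

The default test run completes in ≈3.5 min on one CPU. Trials are
shortened (1–2 s movements, 0.5–1 s rests) and sensor counts reduced
where a property does not depend on scale; the 240-segment offline
protocol check runs at a reduced sampling rate because segment counts are
rate-independent. Package defaults always remain the full protocol
values.

## Known limitations

* The Hampel and relabelling procedures are normative surrogates, not
  reconstructions of the original reference implementations.
* The generator's rest class is stationary; real rest contains postural
  drift and residual tone.
* The controller models no execution latency beyond the window cadence
  and the execution-duration surrogate; hardware delay figures are out of
  scope.
* Offline-scale defaults (40 classes × 6 × 10 s × 12 sensors) produce
  ~58M EMG samples; generating them is feasible but the test suite never
  does so — properties are established at reduced scale.
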