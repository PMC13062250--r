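---
title: "Decoding one-time codes from steady-state visual evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding one-time codes from steady-state visual evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepauth)
```

## The paradigm

A user fixates a single box on a monitor that flickers at one of three
frequencies. Each frequency encodes a digit of a system-generated one-time
code over the alphabet {1, 2, 3}; the box steps through the eight digits of
the code, changing frequency after each decoded digit. The occipital EEG
contains a steady-state visual evoked potential (SSVEP) — an oscillation at
the flicker frequency and its harmonics — and the decoder's job is to read
the digit back from that oscillation, in real time, with no subject-specific
training.

Two codebooks are supported, both built from integer divisors of a 360 Hz
monitor refresh rate:

* **low set**: 1 → 6.67 Hz, 2 → 7.50 Hz, 3 → 8.57 Hz (strong SSVEP
  responses, but visually intrusive flicker);
* **high set**: 1 → 36 Hz, 2 → 40 Hz, 3 → 45 Hz (more comfortable,
  weaker responses).

EEG is sampled at 600 Hz from up to three occipital electrodes (O1, Oz, O2;
the single-electrode condition uses Oz), and arrives in 30-sample blocks —
one block every 50 ms, a 20 Hz update rate.

## Target identification: filter-bank CCA

The decoder is filter-bank canonical correlation analysis (FBCCA). The
buffered EEG `X` (channels × N) is decomposed into sub-bands by zero-phase
Butterworth band-pass filters; each sub-band is compared against a
sine–cosine reference matrix for every candidate frequency $f_k$:

$$
Y_k = \begin{bmatrix}
\sin(2\pi f_k n / f_s) \\
\cos(2\pi f_k n / f_s) \\
\vdots \\
\sin(2\pi H f_k n / f_s) \\
\cos(2\pi H f_k n / f_s)
\end{bmatrix}, \qquad n = 0, 1, \ldots, N - 1,
$$

with $H$ harmonics per reference. The first canonical correlation
$\rho_{k,n}$ between the $n$-th sub-band of `X` and $Y_k$ measures how much
of the buffer's energy is explained by frequency $f_k$; the per-frequency
score fuses sub-bands with a decaying weight,

$$
\tilde\rho_k = \sum_{n=1}^{N_{sb}} w(n)\, \rho_{k,n}, \qquad
w(n) = n^{-a} + b,
$$

with $a = 1.25$, $b = 0.25$. Lower sub-bands retain more reliable SSVEP
content and therefore receive larger weights (1.25, ≈0.671, ≈0.503 for the
three low-set bands).

Per-set parameters:

| parameter | low set | high set |
|---|---|---|
| frequencies (Hz) | 6.67, 7.50, 8.57 | 36, 40, 45 |
| sub-bands (Hz) | 2–60, 12–60, 20–60 | 35–60 |
| reference harmonics H | 4 | 1 |
| weights | $n^{-1.25} + 0.25$ | 1 (single band) |

The high set uses a single band and $H = 1$ because its second harmonics
start at 72 Hz, above the 60 Hz acquisition band limit; with one sub-band
the method reduces to plain CCA on the band-passed buffer, and the weight is
fixed at 1 so that combined scores — and hence the margin threshold — live
on the same scale for both sets.

Two fusion conventions exist in the FBCCA literature: weighted sums of raw
correlations and of squared correlations. The default here is the raw-sum,
because the margin threshold range (0.2–0.5) is calibrated on that scale;
`combine_squared = TRUE` switches to the squared variant.

### Numerical route

The first canonical correlation is computed by the orthogonal
decomposition route: row-mean-center both matrices, take thin QR
decompositions of their transposes with a rank-revealing tolerance
(`tol = 1e-7` relative), and return the largest singular value of
$Q_x^\top Q_y$, clipped to $[0, 1]$. This avoids explicitly forming and
inverting covariance blocks (the brute-force generalized-eigenvalue route is
retained in the test suite as an independent oracle). Rank truncation means
near-degenerate buffers raise errors rather than returning a spurious
$\rho = 1$; an exactly constant channel is rejected as degenerate input.

Reference matrices restart their time index at 0 for every buffer snapshot.
Because CCA with sine/cosine pairs is phase-invariant, alignment with
stimulus onset is immaterial — the test suite asserts score invariance under
buffer-start shifts.

## The streaming decision engine

The engine consumes 30-sample blocks and applies a margin rule:

* evaluations happen once per ingested block (a 20 Hz grid), never on a
  wall clock, so offline replays are bit-reproducible;
* no evaluation occurs before **300 samples** (0.5 s) have accumulated
  since the last reset;
* the buffer slides once it reaches **1800 samples** (3 s), dropping the
  oldest samples;
* a decision fires when the top combined score exceeds the runner-up by at
  least the **threshold** (default 0.30); exact ties go to the lower
  frequency-list index;
* a decision clears the buffer and starts a **0.5 s gaze-shift period**
  during which incoming blocks are discarded — the pause exists to let gaze
  settle, not to pause acquisition, so the simulator keeps producing blocks
  and the engine consumes and drops them.

Per-digit latency counts the collecting phase only. Trial completion time is
the sum of the eight latencies plus the seven inter-digit gaze-shift
windows, matching a trial clock that runs from first stimulus onset to the
final classification. An incorrect decision still advances the trial, so
accuracy is the number of matching digits divided by eight.

There is no decision timeout by default — real sessions simply wait, and
recorded trials can run to hundreds of seconds. An opt-in guard
(`max_duration_s`) either raises an error or force-decides with the current
best score; cohort simulation uses the force-decide variant (20 s cap) so
that low-SNR synthetic subjects cannot stall a run. The feedback display
between digits is modeled as part of the single 0.5 s reset window; no
separate feedback duration is simulated.

## The acquisition front end

The amplifier's digital front end is emulated as a 4th-order Butterworth
band-stop 48–52 Hz (mains notch) followed by a 4th-order Butterworth
band-pass 2–60 Hz. Only the band edges of these filters are prescribed by
the hardware configuration; the Butterworth family and the order of
application (notch, then band-pass — immaterial for LTI filters) are fixed
here for reproducibility. `order` counts poles of the final filter, so an
order-4 band-pass derives from an order-2 low-pass prototype.

All analysis filtering is zero-phase (forward–backward over the buffer
snapshot, odd-reflection padding of `3 * length(a) - 3` samples per end):
the engine re-filters the whole buffer at every 50 ms evaluation, so
zero-phase costs nothing and avoids group-delay distortion. The padding
length is deterministic and buffers shorter than it raise an explicit
error; a causal single-pass mode (`zero_phase = FALSE`) is available for
amplifier-faithful emulation. Note that zero-phase application squares the
magnitude response, which doubles edge attenuation in dB — relevant when
comparing against single-pass specifications.

## The synthetic EEG generator

No public recordings exist for this paradigm, so the package ships a
generative model containing exactly the structures the decoder exploits or
must reject:

* the evoked component: $\sum_{h=1}^{H_c} A\,\delta^{h-1}
  \sin(2\pi h f t + \varphi_h)$ with per-segment random phases
  $\varphi_h$ (CCA is phase-invariant, so phase-locking to a stimulus clock
  would add nothing), harmonic decay $\delta = 0.5$ by default, and
  per-channel SSVEP gains;
* $1/f^\beta$ broadband noise (spectrally shaped white noise, $\beta = 1$
  by default), independently drawn per channel;
* an alpha rhythm (10 Hz sinusoid, per-channel random phase) — deliberately
  adjacent to the low stimulation set, which was chosen to avoid the
  10–15 Hz alpha range;
* optional 50 Hz mains interference, which the front-end notch must remove;
* optional "distractor" sinusoids at the two non-target frequencies
  (default amplitude 0, i.e. pure fixation, since non-target stimuli keep
  flickering on screen but their leakage into occipital EEG is not
  quantified anywhere).

**SNR definition.** Signal strength is specified as `snr_db`, the ratio of
fundamental-component power to background power within ±1 Hz of the
fundamental. The narrowband definition is used because FBCCA sensitivity is
narrowband — broadband SNR would be dominated by irrelevant low-frequency
noise. The fundamental amplitude is derived analytically from the shaped
noise spectrum (plus any interferer falling inside the band), not measured
from a realization, so short segments are calibrated exactly in expectation;
a 60 s validation in the test suite confirms measured SNR within ±1 dB.

**Streaming equals batch.** Noise is synthesized in fixed 7200-sample FFT
chunks consumed sequentially, and sinusoids are functions of the absolute
sample index, so blockwise streaming and single-shot synthesis of the same
seed are sample-identical — the engine can be driven by an interactive
stream whose total length is unknown in advance. The chunking limits the
spectral resolution of the noise model to 1/12 Hz and introduces negligible
chunk-boundary discontinuities; both are irrelevant at the ±1 Hz band scale
the calibration uses.

**Cohort model.** A synthetic subject is a draw of narrowband SNR
(uniform 2–10 dB), per-channel SSVEP gains (Oz fixed at the range maximum
1.0, lateral channels uniform 0.6–1.0), noise gains (0.8–1.2), and alpha
amplitude (0.2–0.8 noise-SD units); high-frequency stimulation receives a
−2 dB SNR offset reflecting the weaker gamma-band response. These ranges are
the package's own choice of a plausible cohort: they produce realistic
qualitative behaviour (three electrodes beat one; decisions take from 0.5 s
up to tens of seconds at low SNR; high-frequency single-electrode is the
hardest condition). They are not fitted to any recorded cohort, and
simulated accuracies and times characterize the simulator, not human data.

What the generator does **not** model: volume conduction, eye blinks and
EMG artifacts, non-stationarity and fatigue across a session, and
inter-digit transient dynamics. Passing tests therefore demonstrate the
correctness of the decoding pipeline and its decision logic under the
assumed signal model — not performance on real recordings.

## Calibration

Per-subject calibration mirrors the experimenter's procedure as a greedy
search: at the current minimum window (starting at 300 samples), sweep the
margin threshold over 0.20–0.50 in 0.05 steps, scoring a batch of
calibration digits per cell; if no threshold reaches the target accuracy,
extend the minimum window by 30 samples and repeat, returning the best cell
seen when the target (100 % by default) is reached or the window grid is
exhausted. The number of calibration digits, the grid steps and the window
cap are configuration ([calibration_config()]) because no canonical values
exist for them; the defaults (8 digits per cell, +30-sample steps, 600
sample cap) keep a full search affordable. Cohort simulation does not
calibrate per subject by default — it runs at the default threshold 0.30 and
300-sample window — keeping cohort results a pure function of the master
seed and the population ranges.

## Summary statistics

Condition summaries report the across-subject mean, sample SD
(n−1 denominator) and the Student-t 95 % confidence interval
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt{n}$. The per-subject table is always
exposed so any alternative convention can be recomputed from it. When the
transcribed 21-subject reference table is summarized this way, the four
condition means reproduce the published values (97/99/96/95 % accuracy;
17.2/38.6/27.1/76.6 s); the published SDs appear to follow a different
convention (likely across trials rather than subjects) and are therefore
recomputed but not treated as reference values.

## Problem sizes in the shipped tests

The test suite validates the CCA implementation against a brute-force
generalized-eigenvalue oracle on 100 random instances; chance-level
behaviour on 300 pure-noise digits; SNR monotonicity on a 5-level grid with
24 digits per level; and a full 21-subject × 4-condition × 4-trial cohort,
whose sub-cohorts are re-run to confirm bit-identical reproduction under
the master seed. These sizes were chosen to make the statistical assertions
sharp while keeping a complete run of the suite a coffee-break affair on a
laptop core.

## Known limitations

* The simulator's channels share one evoked waveform (differing only by
  gain), so spatial filtering gains from CCA are milder than with real
  multichannel geometry.
* Margin thresholds are only meaningful relative to the fusion convention;
  comparing thresholds across `combine_squared` settings is invalid.
* EEG interchange is CSV + JSON sidecar only.
* No information-transfer-rate metric is computed; accuracy and completion
  time are the two reported measures.
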