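---
title: "Measuring nasalance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nasalance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasometry)
```

## The measurement model

Nasalance is the standard objective correlate of perceived nasality: the
percentage of acoustic energy radiated through the nasal cavity relative to
the combined nasal and oral output,

$$\mathrm{nasalance} = 100 \cdot \frac{N}{N + O},$$

measured with two microphones on either side of a separator plate. The
pipeline implemented here mirrors what a real-time nasometer does:

1. both channels pass through the same Butterworth IIR bandpass filter;
2. each channel is sliced into overlapping windowed frames;
3. $N$ and $O$ are the per-frame RMS amplitudes of the windowed samples;
4. frames whose combined energy falls below a sound floor are gated out;
5. the valid-frame ratios form a trajectory; session statistics
   (mean, min, max, sample SD) are computed over valid frames only.

We use the ratio of RMS **amplitudes**, not squared energies. Devices in
this space operationalize frame nasalance as the RMS ratio even where the
definition is phrased in terms of "energy"; the two differ in how they
weight mixed frames but agree at the anchor points 0, 50 and 100%. The
squared-energy alternative is exposed as `compute_trajectory(..., energy =
"squared")`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band edges | 200–800 | Hz | the first-formant region where oral/nasal differences are most informative; matches the analysis band used when validating separator-plate devices |
| filter design order | 2 | — | see below |
| window | 0.05 | s | standard nasometric frame; long enough for stable RMS at 200 Hz (10 cycles), short enough to track syllables |
| overlap | 0.5 | fraction | halves the hop (25 ms) without inflating variance |
| window function | Hann | — | suppresses frame-edge discontinuities; the ratio is insensitive to the window in steady state |
| gate floor | −50 | dBFS | sits well below conversational speech recorded at typical calibration levels (≈ −20 dBFS RMS) yet above electronic noise floors |
| lag window | ±0.5 | s | generous bound on start-time misalignment between sequentially recorded takes |
| LTAS banding | 50 | Hz | one representative level per band over 100–1000 Hz, the conventional display for nasometer frequency-response comparison |

### Filter order semantics

`design_bandpass(low, high, order, fs)` treats `order` as the Butterworth
*design* order — the order of the lowpass prototype, exactly the `n` of
`signal::butter(n, ...)` and `scipy.signal.butter(N, ...)`. The default
`order = 2` therefore yields a bandpass transfer function with four poles,
−3.01 dB at both band edges, and ≈ −29 dB at 50 Hz and 3.2 kHz. We adopted
this convention because it is what practitioners get when they ask those
libraries for a "2nd-order Butterworth bandpass", and because the
single-biquad alternative (−14.6 dB at 50 Hz) provides too little stopband
rejection for the filter's purpose of excluding rumble and high-frequency
channel mismatch from the energy estimates. The single-biquad variant
remains one flag away (`order = 1`).

### Causal vs zero-phase filtering

The trajectory pipeline defaults to a single causal forward pass, faithful
to a streaming real-time implementation; filtering is applied to the whole
signal before framing, which avoids per-frame edge transients and is
equivalent in steady state. Because nasalance is a ratio of two identically
filtered channels, the phase mode barely affects it; `mode = "zero_phase"`
(forward–backward) is available for offline spectral work where group delay
matters.

### Gating details

The gate compares the RMS of the *windowed* combined frame — all samples of
both channels jointly, after the analysis window — against
$10^{\mathrm{floor}/20}$. Using the windowed samples keeps a single framing
pass and one set of frame energies; with a Hann window the frame RMS sits
$\sqrt{3/8}$ (≈ 4.3 dB) below the unwindowed value, so the effective
threshold is correspondingly conservative. Frames with exactly zero total
energy are invalid rather than 0% (the ratio is undefined at $N+O=0$), and
statistics never include invalid frames.

## What the synthetic generator emulates

`generate_dual_recording()` builds both channels from a *single* source
signal split with time-varying weights $w_n = p(t)/100$,
$w_o = 1 - p(t)/100$, so the ideal frame RMS ratio equals the prescribed
profile exactly. Three source kinds are provided: white noise, a 1 kHz
tone, and a "speech-like" source — 200–800 Hz band-limited noise
amplitude-modulated at 4 Hz, exercising the analysis band with
syllable-rate dynamics. Imperfect hardware is modeled by two knobs:

* **leakage**: a frequency-independent symmetric gain
  $\alpha = 10^{-\mathrm{isolation}/20}$ mixes each channel into the other.
  Because both channels share one source, the measured nasalance has the
  closed form `expected_leakage_bias()`:
  $100\,(n+\alpha o)/((n+\alpha o)+(o+\alpha n))$. Leakage compresses the
  scale monotonically toward 50% — a device with poorer isolation reads
  high on oral material and low on nasal material, which is precisely the
  systematic offset observed when low-cost separator-plate devices are
  compared against a better-isolated commercial reference;
* **noise floor**: independent white noise per channel at a configured
  dBFS level.

Monotone time warps (`time_warp_linear`, `time_warp_sine`,
`apply_time_warp`) emulate the speaking-rate variability between two
sequential, non-synchronous recordings of the same material.

What the generator does **not** emulate: spectrally shaped (frequency-
dependent) leakage of a real baffle plate, room reverberation, microphone
directivity and distortion, articulatory detail of real speech, and
recording-to-recording content differences. Passing tests therefore
demonstrate that the *pipeline* is correct and that agreement statistics
behave as designed under controlled misalignment — not that any particular
hardware meets a clinical standard.

## Agreement between non-synchronous recordings

Two trajectories on the same frame hop are compared two ways:

* `r_raw`: the maximum over integer-hop lags $\tau$ (within ±0.5 s) of the
  Pearson correlation between the overlapping, mutually valid frames, with
  means recomputed per overlap. The reported lag is the candidate's shift
  relative to the reference (negative = candidate starts later). Ties break
  toward the smaller |lag|; sub-hop interpolation is not attempted.
* `r_dtw`: classic dynamic time warping on the validity-compacted
  nasalance values — absolute-difference local cost, symmetric steps
  $\{(1,1),(1,0),(0,1)\}$, full boundary conditions, diagonal preferred on
  ties — then the candidate is mapped onto the reference axis by averaging
  all candidate frames matched to each reference frame, and Pearson
  correlation is computed on the aligned pair.

Design choices here were genuinely open and are pinned by oracle tests
rather than inferred: the step pattern is the canonical symmetric one (an
exhaustive dynamic-programming recount on short pairs fixes the
implementation); many-to-one mapping is resolved by averaging because it is
deterministic and order-independent; invalid frames are dropped, not
interpolated, because interpolation would fabricate nasalance values that
were never measured. Note that DTW with unconstrained warping can align
*any* monotone re-timing, so `r_dtw` should be read as "agreement after
removing timing", never as evidence about absolute levels — leakage-induced
scale compression, for instance, is invisible to both correlations.

## Electroacoustic analyses

* **LTAS**: Welch's overlapped averaged periodogram (1-s Hann segments,
  50% overlap), power summed into half-open 50-Hz bands over 100–1000 Hz,
  in dB. The estimator choice matters little at these averaging lengths;
  banding is what makes curves from different hardware comparable.
  `normalize_relative()` subtracts the curve maximum to compare spectral
  *shape* across devices with different gains, and `ltas_mad()` averages
  absolute band differences over 200–800 Hz by default.
* **Intensity gap**: whole-recording RMS level difference (oral − nasal) in
  dB, optionally after bandpass filtering. Levels are dB re digital full
  scale; only *differences* are comparable across systems, so the gap is
  the primary quantity.
* **THD**: harmonic amplitudes are estimated from the Hann-windowed
  spectrum as the root of the power within ±2 bins of each harmonic peak
  (the window's main lobe), making the amplitude *ratio* robust to
  non-integer cycle counts; default 5 harmonics, skipping any at or above
  Nyquist.

## Numerical choices and degenerate inputs

* PCM normalization divides by 32768 (symmetric full scale; −1.0
  reachable); writing quantizes by `round(x · 32768)` clipped to
  \[−32768, 32767\], so read→write round trips are bit-exact and +1.0
  clips to one LSB below full scale. Out-of-range amplitudes are clamped
  with a warning.
* The raw PCM dialect is fixed as 16-bit signed little-endian interleaved
  stereo, headerless, sample rate supplied by the caller (default
  44.1 kHz). Recorders rarely document byte order; this choice is a
  declared convention of the package.
* No resampling is performed anywhere: recordings at different rates are
  compared on frame-time grids, and `trajectory_pair()` insists on a
  common hop.
* Degenerate inputs fail loudly: zero valid frames (fully gated), silent
  channels in `intensity_gap()`, zero variance in either correlation,
  single-frame DTW inputs, non-monotone warps, band edges at or above
  Nyquist.

## Problem sizes in the shipped tests

The test-suite and the reproduction script run entirely on generated audio:
2–6 s recordings at 8–44.1 kHz, 15 leakage-recovery conditions
(five profiles × three isolation levels at a −60 dBFS noise floor), 10–20
random DTW oracle pairs of ≤ 12 frames, and 5–10 s noise signals for the
spectral estimators. These sizes were chosen so each statistic is
comfortably inside its tolerance (e.g. recovery errors ≈ 0.04 pp against a
1 pp bound) while the whole suite completes in seconds.

## Known limitations

* Scalar leakage is a first-order model of a spectrally shaped phenomenon.
* The gate threshold and window defaults are declared conventions, not
  values read off any particular device.
* Agreement measures assume both trajectories were produced with the same
  hop; no sub-hop alignment or open-ended/subsequence DTW is provided.
* Only 16-bit PCM audio is supported; compressed formats and >2-channel
  files are out of scope.
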