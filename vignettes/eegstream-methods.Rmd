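---
title: "Methods: the eegstream acquisition, telemetry and analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eegstream acquisition, telemetry and analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`eegstream` is a software model of a battery-powered 24-channel mobile EEG
acquisition chain and of the resting-state analysis used to validate such
devices. It covers five stages: a synthetic session generator, the
firmware-style digital front end, an adaptive delta codec, bit-exact message
framing, and an eyes-open/eyes-closed spectral contrast analysis. This
vignette records the scientific and numerical decisions behind each stage —
in particular the places where the device behaviour is only loosely
constrained and this package had to commit to a convention.

## The synthetic session generator

No public recordings exist for this class of device, so every downstream
stage is exercised on sessions from `generate_session()`. The generator
emulates the standard validation protocol: a 20-minute session of
alternating 2-minute eyes-closed / eyes-open blocks (starting eyes-closed),
sampled at the internal 500 Hz ADC rate on the 24-channel 10–20 montage
(FP1 … O2, left/right mastoids included).

The signal model, per channel and in microvolts:

* **1/f background** on every channel: spectrally shaped Gaussian noise with
  power slope −1 above 0.1 Hz (flat below, so the variance of long sessions
  stays finite), scaled to a total rms of 10 µV.
* **Mains interference**: a common-phase 50 Hz sinusoid of 5 µV on every
  channel.
* **Occipital alpha**, eyes-closed blocks only, on O1, OZ, O2 and POZ: a
  10 Hz sinusoid, amplitude 20 µV, multiplied by a slow stochastic envelope
  (Gaussian noise smoothed with a 1-s Gaussian kernel, mapped to mean 1,
  sd 0.5, clipped at zero). The envelope produces the waxing-and-waning
  spindles seen in real alpha rather than a pure tone; its parameters are
  free choices — real alpha modulation depth is subject-specific.
* **Frontal delta**, eyes-open blocks only, on FP1, FPZ, FP2, F7, F3, FZ,
  F4, F8: independent Gaussian noise band-passed to 1.5–3.5 Hz and scaled to
  15 µV rms. This reproduces the wakeful eyes-open delta elevation as a
  condition-locked power difference; it makes no claim about its cortical
  mechanism.
* **Blinks**, eyes-open blocks only: a Poisson train (0.25 events/s) of
  transients with the classic frontal blink morphology — a dominant narrow
  positive lobe followed by a wider, shallower undershoot, exactly zero-mean,
  peak 120 µV, duration drawn from 0.3–0.5 s — applied with weight 1 on
  FP1/FPZ/FP2 and 0.3 on the remaining frontal row. An early draft used a
  symmetric biphasic template; that doubles the peak-to-peak excursion
  relative to the nominal peak and is not what frontal EOG artifacts look
  like, so the asymmetric shape was adopted.
* **Saccades**: one 20 Hz damped burst (200 ms, 0.7 × blink amplitude)
  within the first second after each eyes-open onset, emulating the eye
  movement that follows the condition trigger.

What the generator does **not** emulate: volume conduction (components are
pasted onto channel groups with fixed weights, so inter-channel correlation
structure is cruder than real scalp data), ECG/EMG contamination, electrode
drift and impedance changes, and subject-level variability. Tests passing on
these sessions therefore demonstrate that the pipeline recovers known
condition-locked spectral structure through the full telemetry chain — not
that it would behave identically on any particular human recording.

Determinism: all randomness flows from `session_config(seed = ...)` through
a private RNG stream; identical configurations produce bit-identical
sessions and the caller's RNG state is never disturbed.

## The digital front end

`run_frontend()` models the on-chip processing: low-pass filter, band-stop
notch, block-average downsampling, first-order high-pass, and 24-bit
quantization, in that order.

* **Filter family.** The hardware documentation states orders and corner
  frequencies (low-pass 60 Hz order 6; notch 46–54 Hz order 4) but not the
  topology. Both are implemented as Butterworth designs (`signal::butter`):
  maximally flat passbands are the default choice for biosignal front ends,
  and the contract is defined by frequency response, not by coefficients.
* **Causality.** Filters run as causal single passes with zero initial
  conditions — firmware cannot filter acausally. The analysis-side 1–30 Hz
  band-pass (below) is zero-phase, as offline analysis can afford.
* **Downsampling** is block averaging of 2 or 3 consecutive samples
  (trailing partial block dropped), taking 500 Hz to 250 Hz or to the exact
  rational 500/3 Hz. The integer 167 is a display convention; internally the
  exact rate is kept so epoch arithmetic stays consistent. Averaging across
  time is the only reading under which "averaging three samples" can change
  the sampling rate; averaging across the three ADC banks could not.
* **High-pass** (first-order Butterworth, 0.5 Hz, configurable) is applied
  after downsampling, at the output rate, following the documented pipeline
  ordering. The corner is a free choice; 0.5 Hz is a common hardware DC
  restoration corner.
* **Quantization**: `counts = round(v · gain · 2^23 / 2.5)` for the 2.5 V
  reference, clipped to signed 24-bit — clipping is the defined overflow
  behaviour. Gains 1/2/4/8 mirror the device's four settings.
* **Streaming.** `frontend_state()`/`frontend_process()` carry per-channel
  input/output tails and the downsampler remainder, so chunked processing is
  bit-identical to one-shot processing (the suite asserts exact equality).

## The adaptive delta codec

Channel values are transmitted as differences, not absolutes. Per channel,
with reconstruction `r`, shift code `s` and transmitted width `n` ∈
{10, 14, 16}:

    d = x − r
    q = clip( round(d / 2^s), −2^(n−1), 2^(n−1)−1 )   # half-away-from-zero
    r ← r + q · 2^s

* **Closed loop.** Differences are taken against the *encoded* previous
  value, so encoder and decoder reconstructions are bit-identical on a
  lossless stream and clipping cannot accumulate drift. An open-loop design
  (differences against the raw signal) would drift under clipping.
* **Floating average.** The device tracks a per-channel "floating average"
  to decide which bits of the 24-bit difference matter. The exact formula is
  not documented; here it is an exponential moving average of |d| with
  weight λ = 1/fs_out, i.e. a time constant of about one second — matching
  the once-per-second shift-update cadence. The average continues across
  shift updates (resetting it would discard exactly the history the next
  update needs).
* **Shift selection**, once per second per channel:
  `s = max(0, min(15, bitlength(ceil(A · headroom)) − (n − 1)))` — the
  smallest shift such that `headroom` times the average magnitude still fits
  in the transmittable range. The default headroom of 8 places typical
  differences about three bits below full scale: on stationary Gaussian
  differences the max representable value sits near 6.4 standard deviations,
  making clipping vanishingly rare while wasting little resolution. Without
  clipping the per-sample reconstruction error is bounded by `2^(s−1)`
  counts (half a quantization step), which the suite verifies sample by
  sample.
* **Rounding** is half-away-from-zero, so positive and negative differences
  are treated symmetrically. Shifting happens before clipping ("clipped to
  fit within the specified limits" applies to the transmitted value).
* **Startup**: reconstructions start at zero and the first frame is a
  difference from zero. Combined with the front-end high-pass, signals are
  near-zero-mean, so the startup transient is bounded and decays within the
  first shift-update interval.

The per-sample loop and the stream serializer are compiled code (Rcpp); the
exported scalar operations (`encode_frame()`, `decode_frame()`,
`update_shift()`) are an independent pure-R expression of the same
arithmetic, and the suite checks the two paths agree exactly.

## Message framing

Three message kinds exist, with sizes fixed by the device's characteristic
catalogue: data packets of 31/43/49 bytes (10/14/16-bit values), a 14-byte
shift update, an 8-byte configuration/battery readback. Sizes follow
`1 + ceil(24 n / 8)` for the data packets. Inside those totals the bit-level
layout is not published, so this package declares its conventions
explicitly and tests against them:

* Data packet: header byte = packet id (high nibble) | dropped count
  saturated at 15 (low nibble); then 24 two's-complement values, MSB-first,
  bit-contiguous across byte boundaries, any final partial byte zero-padded.
* Shift update: reference packet id, one reserved flags byte, then 24 4-bit
  shifts packed two per byte, even channel index in the high nibble. The
  update is emitted immediately before the first data packet encoded with
  the new shifts, and the decoder applies pending shifts at that packet —
  this synchronizes both sides without timestamps.
* Configuration: gain code (0–3 for 1/2/4/8), rate code (0 = 250 Hz,
  1 = 167 Hz), bit-length code (0/1/2 for 10/14/16), filter mask, battery
  millivolts as unsigned 16-bit big-endian, two reserved bytes.
* Offline container: a flat `[tag][message]` sequence with tags 0x60/0x61/
  0x62 (data), 0xDE (shift update), 0xC0 (configuration).

`simulate_loss()` models transport loss: surviving packets carry the number
of packets lost since the previous delivery, saturated at the 4-bit maximum.

## The resting-state analysis

The analysis chain mirrors standard resting-state practice: zero-phase
1–30 Hz Butterworth band-pass (order 4), per-channel mean subtraction,
bad-channel removal, segmentation into 15-s epochs within condition blocks,
epoch rejection, Hanning-taper PSD, band powers (Delta 1–4, Theta 4–8,
Alpha 8–12, Beta 12–30 Hz, integrated over `[low, high)`), and a
cluster-based permutation test per band.

Decisions worth recording:

* **Taper.** "Multitaper with a Hanning window" is common shorthand for a
  single-Hanning-taper FFT periodogram; that is the default here (density
  scaling, µV²/Hz, resolution 1/15 Hz at 15-s epochs). A true multitaper
  mode (orthonormal sine tapers) is available via
  `compute_psd(taper = "multitaper")` for lower-variance spectra.
* **Baseline** is the whole-recording per-channel mean; no documented
  baseline window exists for this protocol and the band-pass removes DC
  anyway.
* **Bad channels**: robust SD (MAD) above 5× the channel median, or exactly
  zero, after filtering. A channel that is pure DC offset filters to flat
  zero and is therefore removed by the zero-SD rule; `remove_bad = FALSE`
  exposes the filtered signal itself.
* **Epoch rejection** removes epochs whose worst channel exceeds 250 µV
  peak-to-peak. The threshold must sit above the generator's normal blink
  morphology (peak 120 µV plus undershoot plus background, ptp roughly
  170–230 µV on frontal channels) — otherwise essentially every eyes-open
  epoch would be discarded and the eyes-open condition would be untestable —
  yet low enough to catch overlapping-blink excursions and the like. With
  250 µV, all eyes-closed and roughly 70–95% of eyes-open epochs survive
  under default conditions.
* **Adjacency.** Channels are neighbours when closer than 1.75× the median
  nearest-neighbour distance on the 2-D projected montage. On a true 10–20
  layout, smaller multipliers leave the vertex channels (C3/CZ/C4) without
  neighbours and sever outer-ring pairs such as F7–T7 and P7–O1, because the
  posterior midline chain (PZ–POZ–OZ) compresses the median
  nearest-neighbour distance; 1.75 restores the standard ring-and-spoke
  neighbourhood (degrees 3–7, single connected component) while keeping
  anterior–posterior pairs like FP1–O2 unconnected. The mastoids connect to
  their temporal/parietal neighbours by geometry alone.
* **Statistic.** Independent-samples pooled-variance t on log10 band power
  (variance stabilization for power data), epochs treated as independent
  observations — a single-subject fixed-effects design, which is what the
  alternating-block protocol supports. Supra-threshold channels (|t| above
  the two-sided critical value at `cluster_alpha = 0.05`) are joined into
  connected components of equal sign; the cluster score is the sum of member
  t values; the null distribution is the maximum absolute cluster score over
  `n_perm` random label exchanges, and
  `p = (1 + #{null ≥ |observed|}) / (1 + n_perm)` — the standard
  positively-biased permutation p, which keeps p > 0 and valid. A degenerate
  pooled variance is floored at machine epsilon. Band-level results are
  reported without cross-band correction, matching common practice for this
  protocol; treat per-band p values accordingly.

## Problem sizes and numerical tolerances

The test suite runs the full default study conditions where the claim
demands it — ten independent 20-minute sessions for the end-to-end alpha
peak and cluster-stability checks, 1000 permutations for the topographic
contrasts — and deliberately small inputs everywhere else (seconds-long
sessions for structural checks, 10⁴ fuzzed messages per kind for the
framing round trip, 500 null simulations at 500 permutations for the
type-I calibration of the cluster test, for which the acceptance band is
3–8% at a nominal 5%). Floating-point equality is asserted exactly where
the design guarantees it (chunked vs one-shot filtering, codec closed-loop
agreement, pack/unpack identity) and with explicit physical tolerances
elsewhere (1 dB passband ripple, 20 dB notch depth, 5% Parseval recovery,
half-quantization-step codec error).

## Known limitations

* The framing layouts inside the fixed message sizes are this package's
  declared conventions; hardware with a different nibble or bit order would
  interoperate only after adapting them.
* The generator's channel-group construction understates spatial
  correlation; cluster extents on real data will differ.
* The codec model transmits one sample per packet. Real links batch
  several samples per radio notification; the format generalizes, but batch
  framing is not implemented.
* Loss simulation models the drop counter faithfully but the decoder makes
  no attempt at concealment beyond carrying the reconstruction forward;
  after loss, the signal re-centres only at the rate the differences move
  it.
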