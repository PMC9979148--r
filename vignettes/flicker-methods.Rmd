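---
title: "Flicker stimulation and entrainment analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flicker stimulation and entrainment analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerkit)
```

## The problem

Rhythmic sensory stimulation — lights and/or sounds switched on and off at a
fixed rate ("flicker") — entrains neural oscillations at the stimulation
frequency, including in deep structures such as hippocampus, and is being
explored as a noninvasive way to drive brain rhythms in both mice and
humans. Doing this well requires millisecond-precise stimulus synthesis,
blinded experimental protocols, and an analysis chain that can decide,
quickly and per subject, whether entrainment actually occurred.
`flickerkit` implements that tool chain: waveform synthesis with per-cycle
timing logs, task schedules and a blinded assignment protocol, the
preprocessing and multitaper spectral chain, channel- and subject-level
modulation criteria, spike phase-locking statistics, and open-field
behavioral measures — validated end to end on built-in synthetic
generators, so no recording hardware is needed to test any part of it.

## Stimulus model

A periodic flicker stimulus is a square-wave control signal at frequency
$f$ with duty cycle $d$: each cycle is "on" for $d/f$ seconds from the
cycle start. The canonical gamma stimulus is $f = 40$ Hz, $d = 0.5$, i.e.
12.5-ms on-phases. Audio flicker gates a pure sinusoid carrier (10 kHz for
mice, 7–8 kHz for humans, matching the center of each species' hearing
range) with the same square envelope; audio-only stimulation uses $d =
0.04$ so each cycle is a 1-ms click, matching the click trains used for
auditory steady-state responses. Amplitude is unitless in $[0, 1]$:
voltage, lux, and dB calibration belong to the output hardware, not the
control signal.

Sample-boundary convention: a sample is on iff its fractional cycle phase
lies in $[0, d)$, so the first sample of every cycle is on and rising
edges sit exactly at cycle starts. A partial final cycle is generated but
excluded from the cycle log's duty statistics. Default sample rates are
40 kHz for visual control signals and 44.1 kHz for audio (keeping the
10-kHz mouse carrier below Nyquist and making WAV export direct).

The randomized (aperiodic) control condition keeps every on-phase at
exactly 12.5 ms while drawing off-intervals i.i.d. uniform on $[0, 25]$
ms, which matches total light exposure to the periodic condition and
yields per-cycle duty cycles between 33% and 100%. The upper end of the
published duty range (99%) corresponds to off-intervals of about 0.13 ms;
whether off-intervals below that were excluded at generation time is not
stated, so we keep the full $[0, 25]$ ms support and report the realized
duty range in the cycle log rather than resampling. Off-intervals are
quantized to whole samples; at 40 kHz the quantization is 0.025 ms.

`measure_waveform()` is the verification path — the software analogue of
putting the stimulus on an oscilloscope. It thresholds the rectified
signal at half its maximum; for carrier-modulated audio it first closes
sub-carrier-period dips (the $|\sin|$ troughs) detected via the ratio of
the raw to rectified spectral peaks. The fundamental comes from the median
inter-onset interval of the detected rising edges, and duty from the
first-to-last above-threshold span within each cycle. On a sampled sine
burst the half-amplitude crossing is displaced by up to
$\arcsin(0.5)/2\pi$ of a carrier period plus one sample, so a 4%-duty
click train at 44.1 kHz measures at 3.94% — the method's quantization
floor, well inside the printed precision of the 4% figure.

Audiovisual pairing shifts the audio stream by a signed delay quantized to
the nearest sample (the quantization residual is recorded), since
transmission times through the auditory and visual pathways differ and
deliberate offsets can align arrival at cortex. Applying the negative
delay restores onsets exactly.

## Schedules and blinding

Four preprogrammed task types cover the usual designs: a classical task
(every modality × {5.5 Hz, 40 Hz, 80 Hz, random}), a frequency task (up to
26 distinct frequencies), a duration task (one uninterrupted block, e.g.
the 1-h mouse protocol), and a single-pulse task (12.5-ms pulses for
evoked potentials). Trial and rest durations are not prescribed anywhere
authoritative, so they are configurable with defaults of 120 s trials and
30 s rests; trial order is shuffled by the same seeded generator family
used everywhere else.

Blinding follows the protocol in which a non-blinded third party prepares
a subject → condition table that only the stimulation device reads. The
experimenter-facing session is: a fixed test sequence (2 s of 1-Hz
light-and-tone pulses — its existence is prescribed, its content is ours),
a configurable pause during which the experimenter leaves, then the
condition block. The test-sequence prefix is byte-identical across
conditions, so the observable part of a session carries zero condition
information; schedules and logs store the condition only as a salted MD5
code, with plain labels available solely through an explicit unblinding
call.

## Synthetic data: what it emulates, what it does not

The EEG/LFP generator produces per-channel $1/f^\alpha$ background noise
(spectral shaping of white Gaussian noise, unit variance) plus, from
stimulus onset, a sinusoid at the stimulation frequency with phase zero at
onset — the minimal surrogate for a steady-state evoked response
phase-locked to the stimulus. An optional harmonic stack is available, but
the default is a pure sinusoid: the analysis chain only interrogates the
fundamental. Defaults emulate a 32-channel scalp acquisition at 2048 Hz,
16 channels per hemisphere. Spike trains are inhomogeneous Poisson with
rate $\lambda(t) = r(1 + m\cos(2\pi f t - \phi))$, simulated by thinning
(exact for bounded rates). Trajectories alternate reflected random-walk
"move" bouts with "still" bouts whose jitter is confined far below the
inactivity area bound; entering a still bout takes one full-length step so
the preceding move frame never falls inside the stationary region.

What passing tests on these generators shows: the analysis chain computes
the statistics it claims, at the thresholds it claims, with the
false-positive behavior expected under a $1/f$ null. What it does not
show: robustness to artifacts, volume conduction, non-sinusoidal or
adapting responses, electrode impedance drift, or real tracker noise —
none of which the generators model. Results on real recordings depend on
those factors.

## Spectral chain

The preprocessing order is fixed and enforced by `preprocess()`:
downsample → band-pass → (optional Laplacian re-reference) → per-segment
baseline correction → multitaper PSD. Typical bands: 1–100 Hz for scalp
EEG, 1–300 or 2–300 Hz for LFP, 300–6000 Hz for spike extraction;
wide-band probe data (20 kHz) is brought to 2 kHz before LFP analysis.

Filters are Hamming-windowed FIR, with the order chosen so the transition
band is at most 25% of the low cutoff (≥50 dB stop-band, <1 dB pass-band
ripple). A 1-Hz low edge at 2 kHz needs ~27,000 taps, so the symmetric
kernel is applied by FFT convolution with exact group-delay compensation —
zero-phase, $O(n \log n)$. Downsampling applies an anti-alias low-pass at
80% of the new Nyquist before index decimation (polyphase resampling for
non-integer ratios).

Laplacian re-referencing subtracts the mean of spatially adjacent
contacts: interior contact $i$ becomes $x_i - (x_{i-1} + x_{i+1})/2$,
nulling common-mode and linearly varying (volume-conducted) profiles.
Contacts are ordered by `contact_order` within each hemisphere (one shank
per hemisphere). Edge contacts are kept as one-sided differences
($x_0 - x_1$) and flagged in the metadata rather than dropped, which
would cost hemisphere coverage; their noise is ~2× an interior contact's.

Baseline correction subtracts the mean of consecutive non-overlapping
12-s segments per channel — interpreted as DC removal per record segment,
the simplest reading consistent with its description.

The PSD is the mean of five DPSS-tapered periodograms with time-bandwidth
product 3 over 2–100 Hz, reported one-sided in dB
($10\log_{10}$ of power per Hz; the dB reference is input-units²/Hz, as
no absolute reference is prescribed). Tapers are eigenvectors of the
symmetric tridiagonal matrix that commutes with the band-concentration
operator, computed by Sturm-sequence bisection plus inverse iteration
(compiled; $O(n)$ per step, deterministic start vectors, cached per
window length) and cross-checked against an independent implementation to
$10^{-8}$. Using more than $2NW - 1$ tapers triggers a leakage warning.
Zero-power bins are floored at −300 dB.

## Modulation criteria

A channel is modulated when its power at the stimulation frequency is at
least 3 standard deviations above the mean power at neighboring
frequencies (31–39 and 41–49 Hz for a 40-Hz stimulus): $z = (P_{40} -
\mu_{nb})/\sigma_{nb} \ge 3$, inclusive per "at least". All PSD bins whose
centers fall in the neighbor bands (inclusive) contribute; the stimulus
bin is the nearest grid bin. The z-score is computed on dB power, the
scale modulation is reported in; a linear-power option exists. Because
z-scores are shift-invariant, the criterion is unaffected by the unknown
dB reference.

A subject is modulated with at least 3 modulated channels spanning
hemispheres. The published descriptions differ between "at least one
modulated channel in either hemisphere" and "at least one channel in each
hemisphere"; we default to the stricter each-hemisphere reading (the
criterion described as achieved in practice) and expose
`hemisphere_rule = "either"` for the permissive one — neither silently
substitutes for the other.

Detection latency applies the full criterion to windows $[onset, onset +
t]$ growing in 1-s steps and reports the smallest $t$ that satisfies it.
One property worth knowing: with NW = 3 tapers, a $t$-second window has a
concentration half-bandwidth of $3/t$ Hz, so at 1–2-s windows even an
arbitrarily strong 40-Hz response leaks into the 41–49 Hz neighbor band
and the z-score saturates at a shape-determined ceiling (~1.5 at 1 s, ~2.7
at 2 s, ~4.3 at 3 s). Consequently the infinite-SNR latency of this
criterion is 3 s, not 1 s, and latency is non-increasing in amplitude only
below that leakage-saturation regime — both verified in the test suite.
With amplitudes calibrated so per-channel $z \approx 6$ at 10-s windows
(`calibrate_response_amplitude()`), the subject criterion is met in 2–4 s,
comfortably inside the 10-s bound reported for human scalp EEG.

Spike phase locking is summarized by vector strength — the magnitude of
the mean resultant of spike phases relative to the preceding stimulus
onset — with a Rayleigh uniformity test (Zar's finite-$n$ correction).
No specific statistic is prescribed for "firing at a particular phase";
vector strength is the standard operationalization. For a fully modulated
cosine Poisson train the asymptotic vector strength is exactly
$\int(1+\cos\theta)e^{i\theta}d\theta / \int(1+\cos\theta)d\theta = 1/2$,
which the generator/estimator pair reproduces to well under 0.03.

The occluded-condition check runs the channel criterion on a recording
made while the subject is shielded from the stimuli (eye mask, earplugs):
any modulated channel there indicates an electrical artifact rather than
a sensory response, since it is frequency-specific to the stimulator.

## Behavior

Inactivity is movement confined to 0.01% of the arena area for longer
than 0.5 s (strict). The commercial tracker's internal "activity" measure
is proprietary, so the area criterion is operationalized on the tracked
positions: under the default `"box"` method an interval is stationary
while its axis-aligned bounding box fits inside a square of the threshold
area. A raw box-*area* bound would degenerate for collinear paths (a
straight walk across the arena has zero box area), which motivates the
extent form; the `"disc"` alternative bounds the box diagonal by the
diameter of the threshold-area disc and is rotation invariant. Intervals
grow greedily frame by frame; tracking gaps longer than 2.5 median frame
intervals split candidate bouts. At 30 frames/s a bout spanning exactly
0.5 s is not inactivity and 0.6 s is — the classification flips strictly
above 0.5 s, recovered by a boundary scan in the tests. Percent time
active is $100(1 - \text{bout time}/\text{record time})$, so active and
inactive percentages are complementary by construction.

The center zone defaults to the central rectangle of 50% linear
dimensions (the published figure shows but does not dimension it;
configurable), boundary inclusive. Across-condition comparisons use
one-way repeated-measures ANOVA with the subject × condition interaction
as the error term, via `stats::aov`, validated against hand-computed sums
of squares.

## Numerical choices and problem sizes

- Seeds are mandatory for every stochastic step; all generators restore
  the caller's RNG state, and equal seeds give bit-identical output.
- Degenerate inputs: constant signals report duty 1 with the fundamental
  flagged undefined; zero signals are all-off; identical paired trials
  give $d = 0, p = 1$; a constant non-zero paired difference reports
  $d = \pm\infty, p \to 0$ rather than an error; an all-zero RM-ANOVA
  effect reports $F = 0$.
- The test suite sizes simulations to run comfortably on one CPU: 10,000
  random-flicker cycles for the duty/off-interval bounds, 200 seeded 12-s
  single-channel null recordings for the false-positive rate of the 3-SD
  criterion (empirically ≤ 5%), 20 seeded 32-channel 60-s recordings for
  the latency bound, and 600-s spike trains (~30,000 spikes) for the
  vector-strength limits.

## Known limitations

- The steady-state-response surrogate is a pure phase-locked sinusoid;
  harmonic structure, onset transients, and adaptation are not modeled.
- The stationarity operationalization is documented but not identical to
  any commercial tracker's proprietary activity measure.
- The greedy bout segmentation closes an interval where the bound first
  fails; a slowly drifting animal could in principle be segmented
  differently by an overlapping-window definition.
- Edge contacts in the Laplacian are one-sided differences, not true
  Laplacians; treat their localization claims accordingly.
- Hardware control (DAQ/microcontroller output, calibration to lux/dB,
  real-time playback) is out of scope; exported WAV and delimited control
  signals are the hand-off point.
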