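---
title: "Time-domain neural signal models in tempodyne: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain neural signal models in tempodyne}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempodyne)
```

`tempodyne` is a simulation toolkit for a family of time-domain,
signal-centric models of neural information processing: spike-timing codes
and interval statistics, delay-line/coincidence-detector networks, wave
interference, convolution-based holographic associative memory, and a
single-sideband carrier-suppressed (SSBCS) heterodyne cascade of neural
oscillation bands. This vignette documents the models, their assumptions,
the tunable parameters, and the design choices made where the underlying
ideas are stated qualitatively in the literature and a concrete numerical
commitment had to be made. Every empirical statement below is computed by
the package's test suite or acceptance script, nothing else.

## Units and conventions

All times are in seconds, all frequencies in Hz, everywhere. Waveforms are
uniformly sampled real signals (`waveform`); spike trains are strictly
increasing event-time vectors over a finite observation window
(`spike_train`); the empty train is valid. Interval histograms use
half-open bins `[k*bw, (k+1)*bw)`.

## Temporal spike codes

`encode_phase_locked()` converts a waveform into spikes locked to a fixed
signal phase, the way auditory-nerve discharges lock to stimulus fine
structure. Zero-crossing mode emits a spike at each upward threshold
crossing with the time linearly interpolated between samples (sub-sample
precision is cheap and removes a sample-rate bias from interval
statistics); peak mode uses sample-resolution local maxima, since a peak
location moves less than a crossing under interpolation. A greedy
refractory rule then drops any spike closer than the refractory period to
the last accepted one. No phase-locking roll-off with frequency is
modelled: the encoder is deliberately exact, and the (roughly 4 kHz)
physiological limit is the user's responsibility when choosing stimuli.

Interval statistics come in two orders: `"first"` (consecutive-spike
intervals) and `"all"` (all ordered pairs up to `max_lag`), the latter
giving the autocorrelation-like representation that carries periodicity
pitch. Defaults are `bin_width = 0.1` ms and `max_lag = 30` ms, covering
fundamentals down to about 33 Hz at a resolution well below physiological
jitter; both are configurable. `population_interval_distribution()` sums
per-train histograms bin-wise — intervals are strictly within-train, so no
cross-neuron synchrony is assumed.

### F0 estimation and its oracle

`estimate_f0()` scores each candidate lag bin by the histogram mass at the
lag and its first two multiples, normalized by spike count, and returns the
reciprocal of the winning bin's left edge, breaking ties toward the higher
frequency. Two numerical details matter:

* Multiples are read over the *m-fold dilation* of the candidate bin (the
  image of the bin interval under multiplication by m), taking the maximum
  count inside it. Reading a point lag instead misses the containing bin
  whenever the period is not bin-aligned (e.g. a 313 Hz tone with 0.1 ms
  bins).
* Only bins with nonzero mass are candidates: a lag can only be a period
  if intervals actually occur at it. Without this rule a shorter empty lag
  whose dilations graze true interval mass can tie the true period and
  steal the estimate through the tie-break.

The independent reference is `autocorr_f0()`, a brute-force time-domain
autocorrelation peak picker on the waveform itself, with parabolic lag
refinement so its own sample-grid quantization stays below one histogram
bin. The acceptance suite checks interval-based estimates against this
oracle for pure tones across 50-400 Hz and for a 600/800/1000 Hz
missing-fundamental complex, which both routes resolve to 200 Hz.

The missing-fundamental fixture runs through `phase_locked_channels()`, a
minimal peripheral model: 30 log-spaced windowed-sinc band-pass channels
(quality factor 8) each followed by the zero-crossing encoder. It is not a
cochlear model — no compression, adaptation, or realistic filter shapes —
so green tests establish the interval-pooling logic, not auditory realism.

## Interference

`superpose()` forms the pointwise sum of delayed, gain-scaled components,
padding to the longest delayed component so no energy is truncated;
`delay_signal()` keeps the original duration (tail truncated) because its
contract is "the same observation window, seen through a delayed path".
Steady-state metrics exclude the first and last full period of the probe
frequency to avoid onset transients. Amplitudes and phases at a frequency
are measured by least-squares sinusoid fitting (`tone_component()`), which
is exact for any frequency regardless of bin alignment — this is what lets
closed-form checks like the two-path law `A(tau) = 2|cos(pi f tau)|` be
tested at tight tolerances. Coherence in `relative_phase()` is a Welch
magnitude-squared coherence (default 8 segments); under independence its
expectation is about `1/K`, so the independent-noise test uses 16 segments
against a 0.2 bound.

## Timing nets

`coincidence_detect()` scans the pooled, sorted spikes left to right and
emits one event at the mean time of each window (width epsilon, default
5 ms — inside the 1-10 ms binding range commonly quoted) containing spikes
from at least `min_count` distinct trains; consumed spikes are skipped and
an epsilon refractory keeps output events separated. The cluster rule was
chosen over pairwise emission to avoid output bursts when many trains
coincide.

`best_internal_delay()` is the Jeffress-style readout: a correlogram of
pair counts across a tapped delay line, arg-max tap, ties toward the
smallest delay. Taps may be negative (interpreted as delaying the right
train), because the antisymmetry property
`best(l, r) = -best(r, l)` is only meaningful on symmetric tap sets.

`reverberate()` is deliberately austere: the loop is pattern-preserving
and only a scalar strength evolves, as `min(saturation, gain^k)`. Gain
below 1 is the short-term-memory fading regime; above 1, buildup to
saturation. Signal interactions inside loops are delegated to the
interference and holographic modules.

`facilitate_paths()` adds a count-proportional Hebbian increment
(learning_rate x coincidence count, clipped to `[0, w_max]`) per
(tap, input) path, with no depression arm. The reference convention —
`trains[[1]]` is the postsynaptic/reference train, each remaining train one
input column — is the package's own, since only the increment rule itself
is specified by the modelled idea.

## Holographic associative memory

Binding is circular convolution (`bind()`), recall is circular correlation
with the cue (`unbind()`), traces superpose by vector addition, and
`cleanup()` is content-addressable lookup by cosine similarity with an
acceptance threshold (default 0.15: above chance-level correlations at
n >= 1024, below any plausible signal).

Items are **unitary random vectors**: unit-norm real vectors whose DFT
magnitudes are all 1 (`random_items()`). With plain Gaussian vectors the
correlation decode carries irreducible self-noise that caps single-pair
recall correlation near 0.71; with unitary vectors the decode of a single
binding is exact, so all recall noise comes from superposition crosstalk
and deliberate degradation, which is the cleanest way to expose the
capacity and graceful-degradation properties. Consequences worth knowing:
the correct-item recall correlation in a k-pair memory scales like
1/sqrt(k) *independently of n*, while competitor scores shrink like
sqrt(k/n) — so dimension buys discrimination (retrieval accuracy), not a
higher raw correlation. The capacity tests are written accordingly.

Sequences are stored as superposed bindings of `advance(e_i)` with
`e_(i+1)`, where `advance` is a fixed affine index permutation of the cue
vector. A directional marker is necessary because binding is commutative:
without it every recall step retrieves the predecessor exactly as strongly
as the successor and the walk oscillates. A circular shift does *not* work
as the marker — shifts are phase ramps in the Fourier domain and cancel
algebraically out of every pairwise decode — hence the permutation, which
is norm-preserving, decorrelating, and deterministic in the dimension.

`degrade()` zeroes a uniformly random complement of the kept components,
the vector analogue of cutting a piece from a hologram; mean recall
correlation falls smoothly (approximately like sqrt(keep_fraction)) and
stays above the `3/sqrt(n)` chance band down to quarter fragments at
n = 4096. `spike_train_item()` bridges from spike trains: n bins over the
train's span mapped to +-1 and normalized. These bipolar items are not
unitary, so their decodes are approximate — sufficient for cleanup, and
documented as such.

## The SSBCS mixing cascade

`mix()` is pointwise multiplication: two unit sinusoids at F1 < F2 produce
exactly two components, at F2-F1 and F2+F1, each of amplitude 0.5, and
*nothing at F1 or F2* — the generating frequencies are abolished by the
multiplication itself, not by filtering. `ssbcs_select()` removes the sum
sideband with a linear-phase Blackman windowed-sinc FIR (stop-band ~74 dB,
above the 60 dB design floor; the verified suppression floor defaults to
40 dB, acknowledging that real circuits leave remnants). The automatic
cutoff is the geometric mean `sqrt((F2-F1)(F2+F1))`, and the transition
band is sized to clear both sidebands, which fixes the filter order per
stage. Filtering keeps only the fully overlapped convolution region with
the group delay compensated in `t0`, so stage outputs carry no transients
at the cost of shortening by the filter length.

`run_cascade()` chains stages, measuring each emergent carrier with
`dominant_frequency()` (detection on a segment-averaged spectrum with a
6 dB-above-median gate — the averaging is what makes the gate reject white
noise whose extreme periodogram bin alone would pass it — and localization
on the full-resolution periodogram with quadratic interpolation). Each
stage output is renormalized to unit amplitude before the next
multiplication; this is an IF-amplifier-style gain that cannot affect any
frequency or relative suppression, and prevents the amplitude halving per
product from reaching 0.5^7. Defaults are 2000 Hz sampling for 20 s; the
acceptance script uses 40 s so the final ~1 Hz carrier is still resolved
to well under 0.1 Hz after cumulative filter-edge trimming (about 5.6 s
over seven stages).

Two measurement degeneracies are handled explicitly:

* When F2 = 2 F1 (e.g. 180 mixed with 90), the emergent difference
  frequency coincides with F1, so "residual power at F1" is the emergent
  carrier itself; such probes are reported as `NA` rather than as a
  suppression failure.
* The cascade's stage-by-stage arithmetic from 180 Hz with local
  oscillators 90, 45, 24, 10, 6, 2.5, 1.5 Hz yields emergent carriers
  90, 45, 21, 11, 5, **2.5**, 1 Hz. Stage six is 5 - 2.5 = 2.5 Hz; a
  commonly quoted summary of this sequence prints 3 Hz at that position,
  which is inconsistent with its own stage arithmetic. The package
  follows the arithmetic.

`transport_envelope()`/`recover_envelope()` operationalize "the
information rides in the sidebands": amplitude modulation, then full-wave
rectification plus low-pass at half the carrier (scaled by pi/2, the
reciprocal mean of |sin|). The acceptance suite shows a 2 Hz raised-cosine
envelope surviving the 90 to 45 Hz cascade stage with recovered-envelope
correlation above 0.9.

## Synthetic fixtures and reproducibility

`generate_fixture()` produces every input class the mechanisms assume:
pure tones, harmonic complexes, AM tones, homogeneous Poisson trains,
jittered periodic trains, and random bipolar vectors. The generator states
a world rather than tuning one: Poisson rate 100/s and Gaussian timing
jitter of 0.2-1 ms in the tests correspond to ordinary cortical firing
rates and sub-millisecond spike-timing precision; 1024-4096-dimensional
item vectors are the usual operating range for convolution-based
distributed memories. Stochastic fixtures require a seed, restore the
session RNG state afterwards, and are bit-reproducible given (spec, seed).
What the fixtures do *not* emulate: refractoriness in Poisson trains,
rate adaptation, level-dependent phase locking, correlated noise across
channels — so green tests establish the mechanisms' signal logic, not
biological completeness.

The CLI (`cli_main()`, installed wrapper in `inst/cli/`) exposes
subcommands `fixture`, `encode`, `intervals`, `f0`, `interfere`,
`timingnet`, `holomem`, `cascade`; every run logs its effective
parameters, honors `--seed` and `--config` (YAML over documented
defaults), and returns 0/1/2 for success/validation error/usage error.
Reports are byte-identical under identical invocations.

## Known limitations

* One-dimensional signals only; no spatial wavefront propagation across
  excitable sheets.
* The phase-locking encoder has no high-frequency roll-off model.
* Mixing acts on continuous signals; no spike-level implementation of
  multiplication is offered.
* The reverberatory loop does not model regeneration altering the
  circulating pattern.
* WAV support covers mono PCM16/float32 only; fractional sample rates must
  use CSV.
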