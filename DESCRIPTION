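Package: tempodyne
Title: Time-Domain Neural Signal Toolkit: Spike Codes, Timing Nets,
    Holographic Memory, and Oscillatory Mixing Cascades
Version: 0.1.0
Authors@R:
    person("Tempodyne", "Developers", email = "tempodyne@example.org",
           role = c("aut", "cre"))
Description: A simulation toolkit for time-domain, signal-centric models of
    neural information processing. Provides temporal spike codes and
    interspike-interval statistics (first-order and all-order interval
    histograms, population-interval distributions, autocorrelation-like
    pitch estimation including missing-fundamental stimuli), delay-line and
    coincidence-detector timing networks (Jeffress-style cross-correlation,
    reverberatory short-term-memory loops, coincidence-driven path
    facilitation), one-dimensional wave superposition and interference with
    phase and coherence measures, a holographic associative memory built on
    circular convolution binding with content-addressable cleanup, sequence
    recall and graceful degradation, and a single-sideband
    carrier-suppressed (SSBCS) heterodyne mixing cascade that generates a
    descending sequence of emergent oscillation carriers. Includes a
    deterministic synthetic fixture generator, plain-text and WAV signal
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
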