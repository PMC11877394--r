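#' Uniformly sampled waveform
#'
#' A `waveform` is the carrier/stimulus substrate used throughout the
#' package: a real-valued, uniformly sampled signal with a sample rate and a
#' start time. All times are in seconds and all frequencies in Hz.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). Must be
#'   finite and of length >= 1.
#' @param sample_rate Sampling rate in Hz, > 0.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `waveform` with fields `samples`,
#'   `sample_rate` and `t0`.
#' @examples
#' w <- waveform(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), 100)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz, t0 = %g s, duration %.6g s>\n",
              length(x$samples), x$sample_rate, x$t0, duration(x)))
  invisible(x)
}

#' Duration of a waveform or spike train
#'
#' @param x A [waveform()] or [spike_train()].
#' @return Duration in seconds. For a waveform this is
#'   `length(samples) / sample_rate`.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.waveform <- function(x) length(x$samples) / x$sample_rate

#' Sample times of a waveform
#'
#' @param w A [waveform()].
#' @return Numeric vector of sample times in seconds (`t0`-based).
#' @export
wf_times <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$t0 + (seq_along(w$samples) - 1L) / w$sample_rate
}

#' Sinusoid on an explicit time base
#'
#' Convenience constructor used by the mixing cascade and the fixture
#' generator: evaluates `amplitude * sin(2 pi f t + phase)` on a uniform
#' grid.
#'
#' @param freq Frequency in Hz.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param amplitude Peak amplitude (default 1).
#' @param phase Phase offset in radians (default 0).
#' @param t0 Start time in seconds (default 0). The sinusoid is a function
#'   of absolute time, so two sine waves with different `t0` stay mutually
#'   phase-consistent.
#' @return A [waveform()].
#' @export
sine_wave <- function(freq, duration, sample_rate, amplitude = 1,
                      phase = 0, t0 = 0) {
  n <- round(duration * sample_rate)
  t <- t0 + (seq_len(n) - 1L) / sample_rate
  waveform(amplitude * sin(2 * pi * freq * t + phase), sample_rate, t0 = t0)
}

#' Least-squares amplitude and phase of one spectral component
#'
#' Fits `a * cos(2 pi f t) + b * sin(2 pi f t)` by least squares and returns
#' the complex amplitude `a + i b` expressed as the phasor of
#' `A * sin(2 pi f t + phi)`. Exact for any frequency, bin-aligned or not,
#' which makes it the measurement of choice for closed-form amplitude
#' checks.
#'
#' @param w A [waveform()].
#' @param freq Frequency in Hz at which to measure.
#' @return A list with `amplitude` (peak amplitude `A >= 0`) and `phase`
#'   (radians in `(-pi, pi]`, relative to `sin(2 pi f t)`).
#' @export
tone_component <- function(w, freq) {
  stopifnot(inherits(w, "waveform"))
  t <- wf_times(w)
  s <- sin(2 * pi * freq * t)
  c_ <- cos(2 * pi * freq * t)
  fit <- stats::lm.fit(cbind(s, c_), w$samples)
  bs <- fit$coefficients[[1L]]
  bc <- fit$coefficients[[2L]]
  list(amplitude = sqrt(bs^2 + bc^2), phase = atan2(bc, bs))
}

#' Root-mean-square amplitude
#'
#' @param w A [waveform()].
#' @return RMS of the samples.
#' @export
signal_rms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  sqrt(mean(w$samples^2))
}

# Extract the steady-state portion: drop the first and last full period of
# frequency f (edge/onset transients are excluded from closed-form metrics).
steady_state_region <- function(w, freq) {
  n_edge <- ceiling(w$sample_rate / freq)
  n <- length(w$samples)
  if (n - 2L * n_edge < 2L) {
    stop("waveform too short for steady-state analysis at ", freq, " Hz",
         call. = FALSE)
  }
  idx <- (n_edge + 1L):(n - n_edge)
  waveform(w$samples[idx], w$sample_rate, t0 = w$t0 + n_edge / w$sample_rate)
}

#' Steady-state amplitude of a sinusoidal component
#'
#' Measures the peak amplitude at `freq` after excluding the first and last
#' full period, so that onset and offset transients from delayed
#' superpositions do not bias the estimate.
#'
#' @param w A [waveform()].
#' @param freq Frequency in Hz.
#' @return Peak amplitude (>= 0).
#' @export
steady_state_amplitude <- function(w, freq) {
  ss <- steady_state_region(w, freq)
  tone_component(ss, freq)$amplitude
}
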