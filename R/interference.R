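#' Delayed, gain-scaled component of a superposition
#'
#' @param wave A [waveform()].
#' @param delay Transmission delay in seconds, >= 0.
#' @param gain Finite multiplicative gain (default 1).
#' @return An object of class `component`.
#' @export
component <- function(wave, delay = 0, gain = 1) {
  stopifnot(inherits(wave, "waveform"))
  if (!is.finite(delay) || delay < 0) stop("delay must be >= 0", call. = FALSE)
  if (!is.finite(gain)) stop("gain must be finite", call. = FALSE)
  structure(list(wave = wave, delay = as.numeric(delay),
                 gain = as.numeric(gain)), class = "component")
}

# shift samples right by dt, zero-filling the front; fractional shifts use
# linear interpolation. `extend` keeps the tail (superposition) or not
# (fixed-duration delay).
shift_samples <- function(s, fs, dt, extend = FALSE) {
  shift <- dt * fs
  n <- length(s)
  k <- round(shift)
  if (abs(shift - k) < 1e-9) {
    out <- c(numeric(k), s)
  } else {
    k <- ceiling(shift)
    idx <- (seq_len(n + k) - 1L) - shift   # sample positions in input units
    out <- ifelse(idx < 0 | idx > n - 1L, 0, stats::approx(
      x = 0:(n - 1L), y = s, xout = pmin(pmax(idx, 0), n - 1L)
    )$y)
  }
  if (extend) out else out[seq_len(n)]
}

#' Delay a waveform along a transmission path
#'
#' The output at time `t` equals the input at `t - dt`; the region before
#' `dt` is zero and the duration is preserved (the tail is truncated).
#' Fractional-sample delays are linearly interpolated.
#'
#' @param w A [waveform()].
#' @param dt Delay in seconds, >= 0. A delay at or beyond the waveform's
#'   duration yields an all-zero output with a warning.
#' @return A [waveform()] of the same length and sample rate.
#' @export
delay_signal <- function(w, dt) {
  stopifnot(inherits(w, "waveform"))
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (dt >= duration(w)) {
    warning("delay exceeds waveform duration; output is all-zero")
    return(waveform(numeric(length(w$samples)) , w$sample_rate, t0 = w$t0))
  }
  waveform(shift_samples(w$samples, w$sample_rate, dt), w$sample_rate,
           t0 = w$t0)
}

#' Superpose delayed, scaled waveform components
#'
#' Pointwise sum of the delayed, gain-scaled components; the wave-
#' interference primitive. The output spans the longest delayed component
#' and shorter ones are zero-padded, so no energy is truncated. Components
#' must share one sample rate.
#'
#' @param components List of [component()] objects (bare waveforms are
#'   accepted and treated as delay 0, gain 1).
#' @return A [waveform()].
#' @examples
#' w <- sine_wave(10, 1, 1000)
#' peak <- max(superpose(list(component(w), component(w)))$samples)
#' round(peak, 3)  # constructive interference: 2
#' @export
superpose <- function(components) {
  if (!is.list(components) || length(components) == 0L) {
    stop("components must be a non-empty list", call. = FALSE)
  }
  components <- lapply(components, function(x) {
    if (inherits(x, "waveform")) component(x) else x
  })
  if (!all(vapply(components, inherits, logical(1), "component"))) {
    stop("each element must be a component or waveform", call. = FALSE)
  }
  fs <- vapply(components, function(cp) cp$wave$sample_rate, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("all components must share one sample rate", call. = FALSE)
  }
  fs <- fs[1L]
  shifted <- lapply(components, function(cp) {
    cp$gain * shift_samples(cp$wave$samples, fs, cp$delay, extend = TRUE)
  })
  n_out <- max(lengths(shifted))
  total <- numeric(n_out)
  for (s in shifted) total[seq_along(s)] <- total[seq_along(s)] + s
  waveform(total, fs, t0 = components[[1L]]$wave$t0)
}

#' Relative phase and coherence at a frequency
#'
#' The phase difference `phase(w1) - phase(w2)` of the two signals'
#' components at `f` (least-squares phasor fit, wrapped to `(-pi, pi]`),
#' together with the magnitude-squared coherence at `f` estimated by
#' segment-averaged (Welch) cross-spectra. If either signal carries
#' negligible power at `f` the phase is undefined and `NA` is returned
#' with a warning.
#'
#' @param w1,w2 [waveform()] objects with equal sample rates.
#' @param f Frequency in Hz; must be resolvable (`duration >= 4 / f`).
#' @param n_segments Segments for the coherence estimate (default 8).
#'   Under independence the coherence estimate has expectation about
#'   `1 / n_segments`.
#' @param power_tol Minimum component amplitude relative to the signal RMS
#'   for the phase to count as defined (default 1e-3).
#' @return List with `phase` (radians) and `coherence` (in `[0, 1]`).
#' @export
relative_phase <- function(w1, w2, f, n_segments = 8, power_tol = 1e-3) {
  stopifnot(inherits(w1, "waveform"), inherits(w2, "waveform"))
  if (w1$sample_rate != w2$sample_rate) {
    stop("sample rates must match", call. = FALSE)
  }
  if (min(duration(w1), duration(w2)) < 4 / f) {
    stop("waveforms too short to resolve ", f, " Hz", call. = FALSE)
  }
  c1 <- tone_component(w1, f)
  c2 <- tone_component(w2, f)
  und <- c1$amplitude < power_tol * max(signal_rms(w1), .Machine$double.eps) ||
    c2$amplitude < power_tol * max(signal_rms(w2), .Machine$double.eps)
  if (und) {
    warning("negligible power at ", f, " Hz; phase undefined")
    return(list(phase = NA_real_, coherence = NA_real_))
  }
  phase <- (c1$phase - c2$phase + pi) %% (2 * pi) - pi
  if (phase <= -pi) phase <- phase + 2 * pi
  n <- min(length(w1$samples), length(w2$samples))
  seg <- floor(n / n_segments)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  bin <- round(f * seg / w1$sample_rate) + 1L
  sxx <- syy <- 0
  sxy <- 0i
  for (k in seq_len(n_segments)) {
    idx <- ((k - 1L) * seg + 1L):(k * seg)
    x <- stats::fft((w1$samples[idx] - mean(w1$samples[idx])) * win)[bin]
    y <- stats::fft((w2$samples[idx] - mean(w2$samples[idx])) * win)[bin]
    sxx <- sxx + abs(x)^2
    syy <- syy + abs(y)^2
    sxy <- sxy + x * Conj(y)
  }
  coh <- as.numeric(abs(sxy)^2 / (sxx * syy))
  list(phase = phase, coherence = min(max(coh, 0), 1))
}
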