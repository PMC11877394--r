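#' Windowed-sinc low-pass FIR design
#'
#' Linear-phase FIR low-pass using a Blackman window (stop-band rejection
#' ~74 dB, comfortably above the 60 dB design floor used by the mixing
#' cascade). The filter length grows as `5.5 * fs / trans_bw` so the
#' transition band is fully contained in `trans_bw` Hz around the cutoff.
#'
#' @param cutoff -6 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param trans_bw Transition bandwidth in Hz (default `cutoff / 2`).
#' @return Numeric vector of odd length: the filter taps (unit DC gain).
#' @export
fir_lowpass <- function(cutoff, fs, trans_bw = cutoff / 2) {
  stopifnot(cutoff > 0, cutoff < fs / 2, trans_bw > 0)
  n <- ceiling(5.5 * fs / trans_bw)
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- -m:m
  fc <- cutoff / fs
  h <- 2 * fc * sinc(2 * fc * k)
  win <- 0.42 + 0.5 * cos(pi * k / m) + 0.08 * cos(2 * pi * k / m)
  h <- h * win
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Windowed-sinc band-pass FIR design
#'
#' Difference of two Blackman-windowed sinc low-pass kernels, normalized to
#' unit gain at the band center.
#'
#' @param f_lo,f_hi Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param trans_bw Transition bandwidth in Hz (default half the bandwidth).
#' @return Numeric vector of odd length: the filter taps.
#' @export
fir_bandpass <- function(f_lo, f_hi, fs, trans_bw = (f_hi - f_lo) / 2) {
  stopifnot(0 < f_lo, f_lo < f_hi, f_hi < fs / 2, trans_bw > 0)
  n <- ceiling(5.5 * fs / trans_bw)
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- -m:m
  win <- 0.42 + 0.5 * cos(pi * k / m) + 0.08 * cos(2 * pi * k / m)
  h <- (2 * (f_hi / fs) * sinc(2 * (f_hi / fs) * k) -
          2 * (f_lo / fs) * sinc(2 * (f_lo / fs) * k)) * win
  fc <- (f_lo + f_hi) / 2
  gain <- abs(sum(h * exp(-2i * pi * fc / fs * seq_along(h))))
  h / gain
}

#' Apply an FIR filter (zero-phase timing, valid region)
#'
#' FFT-based convolution keeping only the fully overlapped ("valid")
#' region, so the output carries no start-up or tail transient. The
#' linear-phase group delay is compensated by advancing `t0`, leaving the
#' output time-aligned with the input.
#'
#' @param w A [waveform()].
#' @param taps FIR taps of odd length, shorter than the waveform.
#' @return A [waveform()] shortened by `length(taps) - 1` samples.
#' @export
apply_fir <- function(w, taps) {
  stopifnot(inherits(w, "waveform"))
  nt <- length(taps)
  n <- length(w$samples)
  if (nt >= n) {
    stop("filter length (", nt, ") must be below the waveform length (", n, ")",
         call. = FALSE)
  }
  nfft <- stats::nextn(n + nt - 1L, 2)
  full <- Re(stats::fft(stats::fft(c(w$samples, numeric(nfft - n))) *
                          stats::fft(c(taps, numeric(nfft - nt))),
                        inverse = TRUE)) / nfft
  valid <- full[nt:n]
  waveform(valid, w$sample_rate, t0 = w$t0 + (nt - 1) / 2 / w$sample_rate)
}

#' One-sided power spectrum
#'
#' Hann-windowed periodogram (default) normalized so that a unit-amplitude
#' bin-centered sinusoid peaks at power 0.25 regardless of length; only
#' relative (dB) comparisons are made on top of it.
#'
#' @param w A [waveform()].
#' @param window `"hann"` or `"rect"`.
#' @return A list with `freq` (Hz) and `power` (linear units).
#' @export
power_spectrum <- function(w, window = c("hann", "rect")) {
  stopifnot(inherits(w, "waveform"))
  window <- match.arg(window)
  s <- w$samples - mean(w$samples)
  n <- length(s)
  win <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  } else {
    rep(1, n)
  }
  s <- s * win
  sp <- abs(stats::fft(s) / sum(win))^2
  half <- seq_len(floor(n / 2) + 1L)
  list(freq = (half - 1L) * w$sample_rate / n, power = sp[half])
}

#' Dominant spectral frequency
#'
#' Frequency of the strongest spectral peak within `[f_min, f_max]`,
#' refined by quadratic interpolation of log-power over the peak bin and
#' its neighbours. Peak *detection* runs on a segment-averaged (Welch)
#' spectrum, whose variance is low enough that a genuine tone must stand
#' at least 6 dB above the in-band median while the extreme bin of white
#' noise does not; a signal failing the gate returns `NA_real_`
#' (no-estimate). Peak *localization* then uses the full-resolution
#' periodogram. When two bins tie exactly the lower frequency wins.
#' Resolution is about `1 / duration(w)` Hz; accuracy is documented as
#' `+/- max(0.1, 1/duration)` Hz.
#'
#' @param w A [waveform()] with `duration(w) >= 4 / f_min`.
#' @param f_min,f_max Search band in Hz.
#' @return Peak frequency in Hz, or `NA_real_`.
#' @export
dominant_frequency <- function(w, f_min, f_max) {
  stopifnot(inherits(w, "waveform"))
  if (f_min <= 0 || f_max <= f_min) stop("need 0 < f_min < f_max", call. = FALSE)
  if (duration(w) < 4 / f_min) {
    stop("duration must be >= 4 / f_min for stable peak estimation",
         call. = FALSE)
  }
  # detection gate on an averaged spectrum (segments still resolve f_min)
  n_seg <- max(2L, min(8L, floor(duration(w) * f_min / 2)))
  seg_len <- floor(length(w$samples) / n_seg)
  avg <- 0
  for (k in seq_len(n_seg)) {
    seg <- waveform(w$samples[((k - 1L) * seg_len + 1L):(k * seg_len)],
                    w$sample_rate)
    avg <- avg + power_spectrum(seg)$power
  }
  fr_seg <- (seq_along(avg) - 1L) * w$sample_rate / seg_len
  in_band <- which(fr_seg >= f_min & fr_seg <= f_max)
  if (length(in_band) < 3L ||
      max(avg[in_band]) < stats::median(avg[in_band]) * 10^(6 / 10) ||
      max(avg[in_band]) <= 0) {
    return(NA_real_)
  }
  ps <- power_spectrum(w)
  band <- which(ps$freq >= f_min & ps$freq <= f_max)
  if (length(band) < 3L) stop("search band too narrow for the resolution", call. = FALSE)
  p <- ps$power[band]
  i <- which.max(p)
  k <- band[i]
  df <- ps$freq[2L] - ps$freq[1L]
  f_peak <- ps$freq[k]
  if (k > 1L && k < length(ps$power)) {
    lp <- log(pmax(ps$power[(k - 1L):(k + 1L)], .Machine$double.xmin))
    denom <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (denom < 0) {
      delta <- 0.5 * (lp[1L] - lp[3L]) / denom
      if (abs(delta) <= 0.5) f_peak <- f_peak + delta * df
    }
  }
  f_peak
}

#' Residual power at given frequencies, relative to a reference peak
#'
#' Measures how far each frequency's spectral power sits below the power
#' at a reference frequency, in dB. Used to verify SSBCS suppression of the
#' generating frequencies and the sum sideband.
#'
#' @param w A [waveform()].
#' @param freqs Frequencies to probe, Hz.
#' @param f_ref Reference (emergent-carrier) frequency, Hz.
#' @return Numeric vector: dB of each probe relative to the reference
#'   (negative = below the reference). Power is read as the maximum over
#'   the probe bin and its immediate neighbours. A probe within three
#'   spectral-resolution bins of `f_ref` is returned as `NA`: power there
#'   is indistinguishable from the reference peak itself (e.g. when
#'   F2 = 2 F1, so the emergent difference frequency lands exactly on the
#'   local oscillator).
#' @export
residual_db <- function(w, freqs, f_ref) {
  ps <- power_spectrum(w)
  df <- w$sample_rate / length(w$samples)
  peak_at <- function(f) {
    k <- which.min(abs(ps$freq - f))
    idx <- max(1L, k - 1L):min(length(ps$power), k + 1L)
    max(ps$power[idx])
  }
  ref <- peak_at(f_ref)
  vapply(freqs, function(f) {
    if (abs(f - f_ref) <= 3 * df) return(NA_real_)
    10 * log10(peak_at(f) / ref)
  }, numeric(1))
}

#' Spectral peak report
#'
#' Lists local spectral maxima sorted by descending power, a light
#' diagnostic container for CLI reports.
#'
#' @param w A [waveform()].
#' @param n_peaks Maximum number of peaks to report (default 10).
#' @param f_min,f_max Optional band limits in Hz.
#' @return An object of class `spectral_peak_report`: a list with `peaks`
#'   (data.frame of `freq_hz`, `power_db` relative to the strongest peak)
#'   and `resolution_hz`.
#' @export
spectral_peaks <- function(w, n_peaks = 10, f_min = 0, f_max = Inf) {
  ps <- power_spectrum(w)
  p <- ps$power
  n <- length(p)
  is_pk <- p > c(-Inf, p[-n]) & p >= c(p[-1L], -Inf) &
    ps$freq >= f_min & ps$freq <= f_max
  k <- which(is_pk)
  k <- k[order(p[k], decreasing = TRUE)]
  k <- utils::head(k, n_peaks)
  top <- if (length(k)) max(p[k]) else NA_real_
  structure(
    list(peaks = data.frame(freq_hz = ps$freq[k],
                            power_db = 10 * log10(p[k] / top)),
         resolution_hz = w$sample_rate / length(w$samples)),
    class = "spectral_peak_report"
  )
}
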