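#' SSBCS mixer stage configuration
#'
#' One heterodyne stage: a carrier at `f_carrier` (F2) multiplied with a
#' local oscillator at `f_lo` (F1) produces sidebands at F2 - F1 and
#' F2 + F1; a low-pass at `lp_cutoff` keeps only the difference band
#' (single-sideband), and multiplication itself leaves no power at F1 or
#' F2 (carrier suppression). The cutoff must lie strictly between the
#' difference and sum frequencies.
#'
#' @param f_carrier Carrier frequency F2 in Hz, > `f_lo`.
#' @param f_lo Local-oscillator frequency F1 in Hz, > 0.
#' @param lp_cutoff Low-pass cutoff in Hz; default is the geometric mean
#'   `sqrt((F2 - F1) * (F2 + F1))` of the two sidebands.
#' @param suppression_floor Required attenuation (dB) of F1, F2 and
#'   F1 + F2 relative to the difference-band peak (default 40).
#' @return An object of class `mixer_stage`.
#' @export
mixer_stage <- function(f_carrier, f_lo, lp_cutoff = NULL,
                        suppression_floor = 40) {
  if (!(f_carrier > f_lo && f_lo > 0)) {
    stop("need f_carrier > f_lo > 0 (F1 >= F2 would give a zero or negative carrier)",
         call. = FALSE)
  }
  f_diff <- f_carrier - f_lo
  f_sum <- f_carrier + f_lo
  if (is.null(lp_cutoff)) lp_cutoff <- sqrt(f_diff * f_sum)
  if (!(lp_cutoff > f_diff && lp_cutoff < f_sum)) {
    stop("lp_cutoff must lie strictly between F2 - F1 (", f_diff,
         ") and F2 + F1 (", f_sum, ")", call. = FALSE)
  }
  structure(list(f_carrier = f_carrier, f_lo = f_lo, lp_cutoff = lp_cutoff,
                 suppression_floor = suppression_floor),
            class = "mixer_stage")
}

#' Heterodyne (multiplicative) mixing
#'
#' The nonlinear multiplicative operation at the heart of superheterodyne
#' systems: the pointwise product of two equal-length, equal-rate
#' waveforms. For unit sinusoids at F1 and F2 the product contains exactly
#' two components, at F2 - F1 and F2 + F1, each of amplitude 0.5.
#'
#' @param carrier,lo [waveform()] objects with equal sample rate and
#'   length.
#' @return A [waveform()] (the carrier's time base).
#' @export
mix <- function(carrier, lo) {
  stopifnot(inherits(carrier, "waveform"), inherits(lo, "waveform"))
  if (carrier$sample_rate != lo$sample_rate) {
    stop("sample rates must match", call. = FALSE)
  }
  if (length(carrier$samples) != length(lo$samples)) {
    stop("waveform lengths must match", call. = FALSE)
  }
  waveform(carrier$samples * lo$samples, carrier$sample_rate,
           t0 = carrier$t0)
}

#' Single-sideband selection with carrier suppression check
#'
#' Low-pass filters a mixer product so only the F2 - F1 difference band
#' survives. The FIR transition band is sized to clear both the difference
#' band (pass) and the sum band (stop); the generating frequencies carry
#' no product power in the ideal multiplicative mixer, so after filtering
#' all three are expected at or below `suppression_floor` dB under the
#' difference peak (remnants beyond that raise a warning rather than an
#' error, mirroring real SSBCS circuits).
#'
#' @param product A [waveform()], typically from [mix()].
#' @param stage A [mixer_stage()].
#' @param check Verify the suppression floor spectrally (default TRUE).
#' @return The filtered [waveform()] (shortened by the FIR's edges), with
#'   attribute `"residual_db"` giving measured residuals at F1, F2 and
#'   F1 + F2 relative to the difference-band peak. When F2 = 2 F1 the
#'   difference frequency coincides with F1 and the F1 residual is `NA`:
#'   the power there is the emergent carrier itself and a remnant cannot
#'   be distinguished from it.
#' @export
ssbcs_select <- function(product, stage, check = TRUE) {
  stopifnot(inherits(product, "waveform"), inherits(stage, "mixer_stage"))
  f_diff <- stage$f_carrier - stage$f_lo
  f_sum <- stage$f_carrier + stage$f_lo
  trans <- 2 * min(stage$lp_cutoff - f_diff, f_sum - stage$lp_cutoff)
  taps <- fir_lowpass(stage$lp_cutoff, product$sample_rate, trans_bw = trans)
  out <- apply_fir(product, taps)
  if (check) {
    res <- residual_db(out, c(stage$f_lo, stage$f_carrier, f_sum), f_diff)
    names(res) <- c("f1", "f2", "sum")
    if (any(res > -stage$suppression_floor, na.rm = TRUE)) {
      warning(sprintf(
        "suppression floor of %g dB not met (residuals: %s dB)",
        stage$suppression_floor,
        paste(sprintf("%s %.1f", names(res), res), collapse = ", ")))
    }
    attr(out, "residual_db") <- res
  }
  out
}

#' Run an SSBCS oscillatory mixing cascade
#'
#' Chains heterodyne stages: stage k multiplies the running carrier
#' (initially a pure sinusoid at `f_start`) with a local oscillator at
#' `lo_freqs[k]`, selects the difference sideband with an automatic cutoff
#' at the geometric mean of the difference and sum frequencies, measures
#' the emergent carrier with [dominant_frequency()], and feeds the
#' (unit-renormalized) output forward as the next stage's carrier. Each
#' emergent carrier is `F2 - F1` of its stage, so the cascade is strictly
#' frequency-decreasing. A stage whose local oscillator is at or above the
#' incoming carrier is rejected.
#'
#' @param f_start Initial carrier frequency in Hz.
#' @param lo_freqs Local-oscillator frequencies in Hz, one per stage.
#' @param duration Signal duration in seconds (default 20; use 40+ when
#'   the final carriers approach 1 Hz so spectral resolution suffices).
#' @param sample_rate Sampling rate in Hz (default 2000).
#' @param suppression_floor Per-stage suppression requirement in dB
#'   (default 40).
#' @param keep_waveforms Keep each stage's (renormalized) output waveform
#'   in the result (default FALSE).
#' @return An object of class `cascade_result`: a list with `stages` (a
#'   data.frame of `f1`, `f2`, `emergent_hz`, `residual_f1_db`,
#'   `residual_f2_db`, `sum_residual_db`), `final_carrier` (Hz) and,
#'   when requested, `waveforms` (list of per-stage outputs).
#' @examples
#' \donttest{
#' res <- run_cascade(180, c(90, 45, 24, 10, 6, 2.5, 1.5))
#' res$stages$emergent_hz  # 90, 45, 21, 11, 5, 2.5, 1
#' }
#' @export
run_cascade <- function(f_start, lo_freqs, duration = 20,
                        sample_rate = 2000, suppression_floor = 40,
                        keep_waveforms = FALSE) {
  stopifnot(f_start > 0, length(lo_freqs) >= 1L, all(lo_freqs > 0))
  carrier <- sine_wave(f_start, duration, sample_rate)
  f2 <- f_start
  rows <- vector("list", length(lo_freqs))
  waves <- if (keep_waveforms) vector("list", length(lo_freqs))
  for (k in seq_along(lo_freqs)) {
    f1 <- lo_freqs[k]
    stage <- mixer_stage(f2, f1, suppression_floor = suppression_floor)
    lo <- waveform(sin(2 * pi * f1 * wf_times(carrier)),
                   sample_rate, t0 = carrier$t0)
    out <- ssbcs_select(mix(carrier, lo), stage)
    f_diff <- f2 - f1
    emergent <- dominant_frequency(out, f_min = max(f_diff / 2, 2 / duration(out)),
                                   f_max = stage$lp_cutoff)
    if (is.na(emergent)) {
      stop("stage ", k, ": no emergent carrier detected", call. = FALSE)
    }
    res <- attr(out, "residual_db")
    rows[[k]] <- data.frame(stage = k, f1 = f1, f2 = f2,
                            emergent_hz = emergent,
                            residual_f1_db = res[["f1"]],
                            residual_f2_db = res[["f2"]],
                            sum_residual_db = res[["sum"]])
    # renormalize to unit amplitude before the next multiplication (each
    # product halves the amplitude; an IF gain stage undoes that)
    amp <- tone_component(out, emergent)$amplitude
    carrier <- waveform(out$samples / amp, sample_rate, t0 = out$t0)
    if (keep_waveforms) waves[[k]] <- carrier
    f2 <- emergent
  }
  structure(list(stages = do.call(rbind, rows), final_carrier = f2,
                 duration = duration, sample_rate = sample_rate,
                 waveforms = waves),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result: %d stage(s), final carrier %.4g Hz>\n",
              nrow(x$stages), x$final_carrier))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

# conservative envelope bandwidth: highest frequency whose power is within
# 40 dB of the envelope spectrum's peak
envelope_bandwidth <- function(envelope) {
  ps <- power_spectrum(envelope)
  if (all(ps$power == 0)) return(0)
  keep <- ps$power >= max(ps$power) * 1e-4
  max(ps$freq[keep])
}

#' Transport an envelope on an oscillatory carrier
#'
#' Amplitude modulation: the information-bearing envelope rides in the
#' sidebands around `f_carrier`, not in the carrier itself. The envelope
#' bandwidth must stay below `f_carrier / 2` so demodulation can separate
#' envelope from carrier.
#'
#' @param envelope A [waveform()]; expected non-negative (a bias is not
#'   added automatically).
#' @param f_carrier Carrier frequency in Hz.
#' @return A [waveform()]: `envelope * sin(2 pi f_carrier t)`.
#' @export
transport_envelope <- function(envelope, f_carrier) {
  stopifnot(inherits(envelope, "waveform"))
  bw <- envelope_bandwidth(envelope)
  if (bw >= f_carrier / 2) {
    stop("envelope bandwidth (", signif(bw, 3),
         " Hz) must be below f_carrier / 2", call. = FALSE)
  }
  t <- wf_times(envelope)
  waveform(envelope$samples * sin(2 * pi * f_carrier * t),
           envelope$sample_rate, t0 = envelope$t0)
}

#' Recover an envelope from a modulated carrier
#'
#' Classic AM demodulation: full-wave rectification followed by a low-pass
#' at `f_carrier / 2`, scaled by `pi / 2` (the inverse of the mean of
#' |sin|) so a constant envelope is recovered at its own level.
#'
#' @param modulated A [waveform()] carrying an amplitude-modulated signal.
#' @param f_carrier Carrier frequency in Hz.
#' @return A [waveform()], shortened by the demodulation filter's edges.
#' @export
recover_envelope <- function(modulated, f_carrier) {
  stopifnot(inherits(modulated, "waveform"))
  rect <- waveform(abs(modulated$samples), modulated$sample_rate,
                   t0 = modulated$t0)
  taps <- fir_lowpass(f_carrier / 2, modulated$sample_rate,
                      trans_bw = f_carrier / 2)
  out <- apply_fir(rect, taps)
  waveform(out$samples * pi / 2, out$sample_rate, t0 = out$t0)
}

#' Correlate two waveforms on their common time support
#'
#' Pearson correlation after interpolating `b` onto `a`'s sample times,
#' restricted to the overlapping window with `edge` seconds trimmed at
#' each end (filters shift and shorten signals, so direct sample-wise
#' comparison is rarely aligned).
#'
#' @param a,b [waveform()] objects.
#' @param edge Seconds trimmed from each end of the overlap (default 0.25).
#' @return Correlation coefficient.
#' @export
wf_correlate <- function(a, b, edge = 0.25) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"))
  ta <- wf_times(a)
  tb <- wf_times(b)
  lo <- max(ta[1L], tb[1L]) + edge
  hi <- min(ta[length(ta)], tb[length(tb)]) - edge
  if (hi <= lo) stop("no overlapping support after edge trimming", call. = FALSE)
  idx <- ta >= lo & ta <= hi
  bi <- stats::approx(tb, b$samples, xout = ta[idx])$y
  stats::cor(a$samples[idx], bi)
}

#' Canonical oscillation-band center frequencies
#'
#' The named band centers used by the default cascade configuration:
#' very high gamma 180, high gamma 90, gamma 45, beta 24, alpha 10,
#' theta 6, delta 2.5 and low delta 1.5 Hz.
#'
#' @return Named numeric vector of center frequencies in Hz.
#' @export
oscillation_bands <- function() {
  c(very_high_gamma = 180, high_gamma = 90, gamma = 45, beta = 24,
    alpha = 10, theta = 6, delta = 2.5, low_delta = 1.5)
}
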