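#' Spike train
#'
#' An ordered list of event (spike) times over a finite observation
#' duration; the neural-code substrate of the package. An empty train is
#' valid.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.
#' @param duration Observation duration in seconds; must be at least the
#'   last spike time. Defaults to the last spike time (0 for an empty
#'   train).
#' @return An object of class `spike_train` with fields `times` and
#'   `duration`.
#' @export
spike_train <- function(times = numeric(0), duration = NULL) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times) && times[1L] < 0) {
    stop("spike times must be non-negative", call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- if (length(times)) times[length(times)] else 0
  }
  if (length(times) && duration < times[length(times)]) {
    stop("duration must be >= the last spike time", call. = FALSE)
  }
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
duration.spike_train <- function(x) x$duration

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %.6g s>\n",
              length(x$times), x$duration))
  invisible(x)
}

#' Number of spikes
#' @param st A [spike_train()].
#' @return Integer spike count.
#' @export
n_spikes <- function(st) {
  stopifnot(inherits(st, "spike_train"))
  length(st$times)
}

#' Shift a spike train in time
#'
#' Adds `dt` to every spike time; spikes shifted outside `[0, duration]`
#' are dropped. Used by delay lines and the Jeffress correlator.
#'
#' @param st A [spike_train()].
#' @param dt Shift in seconds (may be negative).
#' @return A [spike_train()] with the same duration.
#' @export
shift_train <- function(st, dt) {
  stopifnot(inherits(st, "spike_train"))
  t <- st$times + dt
  spike_train(t[t >= 0 & t <= st$duration], st$duration)
}

#' Phase-locked spike encoding of a waveform
#'
#' Converts a waveform into a spike train whose spike times are locked to a
#' fixed phase of the signal, mimicking phase-locked neural discharge. In
#' `"zero-crossing"` mode a spike is emitted at every upward crossing of
#' `threshold`, with the crossing time linearly interpolated between
#' samples; in `"peak"` mode a spike is emitted at every local maximum
#' whose amplitude is at least `threshold`, at sample resolution. A
#' refractory period suppresses any spike closer than `refractory` seconds
#' to the previously accepted spike (greedy, left to right).
#'
#' @param w A [waveform()] with finite samples.
#' @param mode `"zero-crossing"` (default) or `"peak"`.
#' @param threshold Amplitude threshold (finite; default 0).
#' @param refractory Refractory period in seconds, >= 0 (default 0).
#' @return A [spike_train()] with `duration = duration(w)`. Spike times are
#'   relative to the start of the waveform.
#' @examples
#' w <- sine_wave(100, 1, 8000)
#' n_spikes(encode_phase_locked(w))  # 100: one spike per cycle
#' @export
encode_phase_locked <- function(w, mode = c("zero-crossing", "peak"),
                                threshold = 0, refractory = 0) {
  stopifnot(inherits(w, "waveform"))
  mode <- match.arg(mode)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (!is.finite(refractory) || refractory < 0) {
    stop("refractory must be a non-negative number", call. = FALSE)
  }
  s <- w$samples
  n <- length(s)
  fs <- w$sample_rate
  if (mode == "zero-crossing") {
    # upward crossing between i and i+1: s[i] <= thr < s[i+1];
    # a sample exactly at threshold spikes at its own time.
    i <- which(s[-n] <= threshold & s[-1L] > threshold)
    if (length(i)) {
      frac <- (threshold - s[i]) / (s[i + 1L] - s[i])
      t <- (i - 1L + frac) / fs
    } else {
      t <- numeric(0)
    }
  } else {
    i <- which(s > c(Inf, s[-n]) & s >= c(s[-1L], Inf) & s >= threshold)
    t <- (i - 1L) / fs
  }
  if (refractory > 0 && length(t) > 1L) {
    keep <- logical(length(t))
    last <- -Inf
    for (k in seq_along(t)) {
      if (t[k] - last >= refractory) {
        keep[k] <- TRUE
        last <- t[k]
      }
    }
    t <- t[keep]
  }
  spike_train(t, duration = duration(w))
}

#' Interspike-interval histogram
#'
#' Bins interspike intervals of a single train into half-open bins
#' `[k * bin_width, (k+1) * bin_width)`. With `order = "first"` only
#' consecutive-spike intervals are counted; with `order = "all"` every
#' ordered spike pair with separation below `max_lag` contributes, giving
#' the autocorrelation-like all-order interval distribution.
#'
#' @param st A [spike_train()].
#' @param order `"first"` or `"all"`.
#' @param max_lag Largest lag represented, seconds; must exceed
#'   `bin_width`.
#' @param bin_width Bin width in seconds, > 0. Default 0.1 ms.
#' @return An object of class `interval_histogram` with fields `counts`
#'   (length `ceiling(max_lag / bin_width)`), `bin_width`, `max_lag`,
#'   `order`, `n_spikes` and `n_trains`.
#' @examples
#' st <- spike_train(c(0, 0.01, 0.02))
#' interspike_intervals(st, "all", max_lag = 0.05, bin_width = 0.001)$counts[c(11, 21)]
#' @export
interspike_intervals <- function(st, order = c("first", "all"),
                                 max_lag = 0.03, bin_width = 1e-4) {
  stopifnot(inherits(st, "spike_train"))
  order <- match.arg(order)
  if (!(max_lag > bin_width && bin_width > 0)) {
    stop("need max_lag > bin_width > 0", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(max_lag / bin_width))
  t <- st$times
  if (length(t) < 2L) {
    ivals <- numeric(0)
  } else if (order == "first") {
    ivals <- diff(t)
  } else {
    # all ordered pairs within max_lag: for each spike i the window of
    # later spikes reachable is found in O(n log n) overall
    hi <- findInterval(t + max_lag, t)
    len <- pmax(hi - seq_along(t), 0L)
    i <- rep.int(seq_along(t), len)
    j <- sequence(len, from = seq_along(t) + 1L)
    ivals <- t[j] - t[i]
  }
  ivals <- ivals[ivals < n_bins * bin_width]
  # epsilon guard: an interval mathematically equal to a bin edge must not
  # fall one bin low through floating-point division (e.g. 0.02 / 1e-4)
  counts <- tabulate(floor(ivals / bin_width + 1e-9) + 1L, nbins = n_bins)
  structure(
    list(counts = counts, bin_width = bin_width, max_lag = max_lag,
         order = order, n_spikes = length(t), n_trains = 1L),
    class = "interval_histogram"
  )
}

#' @export
print.interval_histogram <- function(x, ...) {
  cat(sprintf(
    "<interval_histogram: order=%s, %d bins of %g ms, %d intervals from %d spikes/%d train(s)>\n",
    x$order, length(x$counts), x$bin_width * 1e3, sum(x$counts), x$n_spikes,
    x$n_trains))
  invisible(x)
}

#' Left edges of histogram bins
#' @param h An [interspike_intervals()] histogram.
#' @return Numeric vector of bin left edges in seconds.
#' @export
histogram_lags <- function(h) {
  stopifnot(inherits(h, "interval_histogram"))
  (seq_along(h$counts) - 1L) * h$bin_width
}

#' Population-interval distribution
#'
#' Pools interval histograms across a population of spike trains by
#' bin-wise summation. Intervals are computed strictly within each train
#' (no cross-train pairs), so no spike-time synchronization across the
#' population is assumed or required.
#'
#' @param trains Non-empty list of [spike_train()] objects.
#' @inheritParams interspike_intervals
#' @return An `interval_histogram`; `n_spikes` and `n_trains` accumulate
#'   over the population.
#' @export
population_interval_distribution <- function(trains, order = c("first", "all"),
                                             max_lag = 0.03,
                                             bin_width = 1e-4) {
  if (!is.list(trains) || length(trains) == 0L) {
    stop("trains must be a non-empty list of spike_train objects",
         call. = FALSE)
  }
  order <- match.arg(order)
  hs <- lapply(trains, interspike_intervals, order = order,
               max_lag = max_lag, bin_width = bin_width)
  out <- hs[[1L]]
  out$counts <- Reduce(`+`, lapply(hs, `[[`, "counts"))
  out$n_spikes <- sum(vapply(hs, `[[`, integer(1), "n_spikes"))
  out$n_trains <- length(hs)
  out
}

#' Fundamental-frequency estimate from an interval histogram
#'
#' Autocorrelation-style pitch estimate: for each candidate lag bin in
#' `[1/f_max, 1/f_min]` a salience is formed by summing the histogram mass
#' at the lag and at its first two multiples (counts are read over the
#' m-fold dilation of the candidate bin so period multiples are never
#' missed by bin quantization), normalized by the spike count. The
#' estimate is `1 / lag` at the maximizing bin's left edge; ties break
#' toward the shorter lag, i.e. the higher frequency.
#'
#' @param h An all-order (recommended) [interspike_intervals()] histogram.
#' @param f_min,f_max Search range in Hz; `1/f_min` must be resolvable
#'   within the histogram (`3/f_min <= max_lag` is not required, but
#'   `1/f_min` must be) and `1/f_max >= bin_width`.
#' @return Estimated F0 in Hz, or `NA_real_` when the histogram is empty
#'   (no-estimate).
#' @export
estimate_f0 <- function(h, f_min = 50, f_max = 400) {
  stopifnot(inherits(h, "interval_histogram"))
  if (f_min <= 0 || f_max <= f_min) stop("need 0 < f_min < f_max", call. = FALSE)
  if (1 / f_min > h$max_lag) {
    stop("1/f_min exceeds the histogram's lag range", call. = FALSE)
  }
  if (1 / f_max < h$bin_width) {
    stop("1/f_max is below the histogram's bin width", call. = FALSE)
  }
  if (sum(h$counts) == 0L) return(NA_real_)
  dt <- h$bin_width
  n_bins <- length(h$counts)
  # candidate bins: left edge in [1/f_max, 1/f_min]
  ks <- which(histogram_lags(h) >= 1 / f_max & histogram_lags(h) <= 1 / f_min)
  ks <- ks[ks > 1L]  # lag 0 is not a period
  # a lag can only be the period if intervals actually occur at it; without
  # this, a bin whose dilations graze true interval mass could tie the truth
  ks <- ks[h$counts[ks] > 0L]
  if (!length(ks)) return(NA_real_)
  if (!length(ks)) stop("no candidate lag bins in [1/f_max, 1/f_min]", call. = FALSE)
  salience <- vapply(ks, function(k) {
    s <- h$counts[k]
    for (m in 2:3) {
      lo <- floor(m * (k - 1L)) + 1L
      hi <- min(ceiling(m * k), n_bins)
      if (lo <= n_bins) s <- s + max(h$counts[lo:hi])
    }
    s / h$n_spikes
  }, numeric(1))
  k_star <- ks[which.max(salience)]  # first max = shortest lag = highest f
  1 / ((k_star - 1L) * dt)
}

#' Band-pass channel bank with phase-locked encoding
#'
#' A minimal model of a peripheral filter bank: `n_channels` windowed-sinc
#' band-pass filters with log-spaced center frequencies, each followed by
#' the phase-locked zero-crossing encoder. Supports missing-fundamental
#' demonstrations: each channel locks to the partial dominating its band,
#' and the pooled all-order interval distribution carries the common
#' fundamental period.
#'
#' @param w A [waveform()].
#' @param n_channels Number of channels (default 30).
#' @param f_lo,f_hi Center-frequency range in Hz (defaults 100 and 3000).
#' @param q Filter quality factor: bandwidth = center / `q` (default 8).
#' @param threshold,refractory Passed to [encode_phase_locked()].
#' @return List of [spike_train()] objects, one per channel.
#' @export
phase_locked_channels <- function(w, n_channels = 30, f_lo = 100,
                                  f_hi = 3000, q = 8, threshold = 0,
                                  refractory = 0) {
  stopifnot(inherits(w, "waveform"))
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_channels))
  lapply(cf, function(f) {
    bw <- f / q
    filt <- fir_bandpass(f - bw / 2, f + bw / 2, w$sample_rate,
                         trans_bw = bw)
    encode_phase_locked(apply_fir(w, filt), mode = "zero-crossing",
                        threshold = threshold, refractory = refractory)
  })
}

#' Brute-force autocorrelation F0 oracle
#'
#' Direct time-domain autocorrelation peak picking on the waveform itself,
#' independent of spike encoding and interval histograms. Serves as the
#' reference estimator against which the interval-based route is validated.
#'
#' @param w A [waveform()].
#' @param f_min,f_max Search range in Hz.
#' @return Frequency (Hz) of the maximal autocorrelation lag in
#'   `[1/f_max, 1/f_min]`.
#' @export
autocorr_f0 <- function(w, f_min = 50, f_max = 400) {
  stopifnot(inherits(w, "waveform"))
  s <- w$samples - mean(w$samples)
  fs <- w$sample_rate
  lag_min <- max(1L, round(fs / f_max))
  lag_max <- min(length(s) - 1L, round(fs / f_min))
  if (lag_max <= lag_min) stop("waveform too short for the F0 range", call. = FALSE)
  # biased (undivided) autocorrelation: on periodic signals the taper makes
  # the fundamental lag strictly dominate its multiples, and which.max's
  # first-maximum rule breaks any residual tie toward the shorter lag
  ac <- vapply(lag_min:lag_max, function(L) {
    n <- length(s) - L
    sum(s[1:n] * s[(L + 1):(L + n)])
  }, numeric(1))
  i <- which.max(ac)
  lag <- (lag_min:lag_max)[i]
  # parabolic refinement frees the oracle from the sample grid
  if (i > 1L && i < length(ac)) {
    denom <- ac[i - 1L] - 2 * ac[i] + ac[i + 1L]
    if (denom < 0) {
      delta <- 0.5 * (ac[i - 1L] - ac[i + 1L]) / denom
      if (abs(delta) <= 0.5) lag <- lag + delta
    }
  }
  fs / lag
}
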