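#' Coincidence detector
#'
#' An element that emits an event when spikes from enough distinct input
#' trains fall inside a short temporal window. The default 5 ms window sits
#' inside the 1-10 ms range usually quoted for synchronous neural binding.
#'
#' @param window Coincidence window epsilon in seconds, > 0 (default
#'   0.005).
#' @param min_count Minimum number of distinct contributing trains,
#'   integer >= 2 (default 2).
#' @return An object of class `coincidence_detector`.
#' @export
coincidence_detector <- function(window = 0.005, min_count = 2L) {
  if (!is.finite(window) || window <= 0) stop("window must be > 0", call. = FALSE)
  min_count <- as.integer(min_count)
  if (min_count < 2L) stop("min_count must be >= 2", call. = FALSE)
  structure(list(window = window, min_count = min_count),
            class = "coincidence_detector")
}

#' Tapped delay line
#'
#' An ordered set of internal transmission delays. Taps may be negative:
#' a negative tap stands for delaying the contralateral (right) input,
#' which makes symmetric tap sets possible for Jeffress-style binaural
#' cross-correlation.
#'
#' @param taps Numeric vector of delays in seconds, strictly increasing.
#' @return An object of class `delay_line`.
#' @export
delay_line <- function(taps) {
  taps <- as.numeric(taps)
  if (length(taps) == 0L || anyNA(taps)) stop("taps must be non-empty", call. = FALSE)
  if (is.unsorted(taps, strictly = TRUE)) {
    stop("taps must be strictly increasing", call. = FALSE)
  }
  structure(list(taps = taps), class = "delay_line")
}

#' Reverberatory loop
#'
#' A recurrent delay path that regenerates a circulating spike pattern.
#' Per cycle the pattern's scalar strength is multiplied by `gain`; gain
#' below 1 gives the gradual fading of reverberatory short-term memory,
#' gain above 1 builds up to `saturation`.
#'
#' @param loop_delay Circulation time in seconds, > 0.
#' @param gain Per-cycle multiplicative gain, >= 0.
#' @param saturation Strength ceiling, > 0 (default 1e3).
#' @return An object of class `recurrent_loop`.
#' @export
recurrent_loop <- function(loop_delay, gain, saturation = 1e3) {
  if (!is.finite(loop_delay) || loop_delay <= 0) {
    stop("loop_delay must be > 0", call. = FALSE)
  }
  if (!is.finite(gain) || gain < 0) stop("gain must be >= 0", call. = FALSE)
  if (!is.finite(saturation) || saturation <= 0) {
    stop("saturation must be > 0", call. = FALSE)
  }
  structure(list(loop_delay = loop_delay, gain = gain,
                 saturation = saturation), class = "recurrent_loop")
}

#' Per-path synaptic weights for coincidence-driven facilitation
#'
#' Weights indexed by (delay-line tap, input train); all bounded in
#' `[0, w_max]`.
#'
#' @param taps Numeric vector of tap delays (seconds), strictly
#'   increasing.
#' @param n_inputs Number of (non-reference) input trains.
#' @param learning_rate Weight increment per coincidence event, > 0.
#' @param w_max Upper weight bound (default 1).
#' @param weights Optional initial weight matrix (`length(taps)` x
#'   `n_inputs`), defaults to all zero.
#' @return An object of class `path_weights`.
#' @export
path_weights <- function(taps, n_inputs, learning_rate = 0.01, w_max = 1,
                         weights = NULL) {
  taps <- as.numeric(taps)
  if (is.unsorted(taps, strictly = TRUE)) {
    stop("taps must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- matrix(0, nrow = length(taps), ncol = n_inputs)
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != length(taps) || ncol(weights) != n_inputs) {
    stop("weights must be length(taps) x n_inputs", call. = FALSE)
  }
  if (any(weights < 0) || any(weights > w_max)) {
    stop("weights must lie in [0, w_max]", call. = FALSE)
  }
  structure(list(weights = weights, taps = taps,
                 learning_rate = learning_rate, w_max = w_max),
            class = "path_weights")
}

#' Detect spike coincidences across trains
#'
#' Scans the pooled, time-sorted spikes left to right. Whenever a window of
#' width epsilon starting at an unconsumed spike contains spikes from at
#' least `min_count` distinct trains, one output event is emitted at the
#' mean time of the spikes in that window; the window's spikes are then
#' consumed and an epsilon refractory keeps output events at least epsilon
#' apart.
#'
#' @param trains List of two or more [spike_train()] objects.
#' @param det A [coincidence_detector()].
#' @return A [spike_train()] of coincidence events whose duration is the
#'   maximum input duration.
#' @export
coincidence_detect <- function(trains, det = coincidence_detector()) {
  if (!is.list(trains) || length(trains) < 2L) {
    stop("need at least two spike trains", call. = FALSE)
  }
  stopifnot(inherits(det, "coincidence_detector"))
  times <- unlist(lapply(trains, `[[`, "times"))
  ids <- rep(seq_along(trains),
             vapply(trains, function(s) length(s$times), integer(1)))
  dur <- max(vapply(trains, `[[`, numeric(1), "duration"))
  if (length(times) == 0L) return(spike_train(numeric(0), dur))
  o <- order(times)
  times <- times[o]
  ids <- ids[o]
  eps <- det$window
  out <- numeric(0)
  last_emit <- -Inf
  i <- 1L
  n <- length(times)
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1L] - times[i] <= eps) j <- j + 1L
    if (length(unique(ids[i:j])) >= det$min_count) {
      ev <- mean(times[i:j])
      if (ev - last_emit >= eps) {
        out <- c(out, ev)
        last_emit <- ev
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  spike_train(out, dur)
}

#' Jeffress-style best internal delay
#'
#' Cross-correlates two spike trains over a tapped delay line: for each
#' tap `tau` the correlogram counts spike pairs with
#' `|left + tau - right| <= eps`. The external time difference is read out
#' as the arg-max tap; exact ties break toward the smallest tap.
#'
#' @param left,right Non-empty [spike_train()] objects.
#' @param line A [delay_line()]; negative taps delay the right train.
#' @param eps Pair-matching tolerance in seconds (default 0.5 ms).
#' @return List with `delay` (seconds) and `correlogram` (integer counts,
#'   one per tap, named by tap delay).
#' @export
best_internal_delay <- function(left, right, line, eps = 5e-4) {
  stopifnot(inherits(left, "spike_train"), inherits(right, "spike_train"),
            inherits(line, "delay_line"))
  if (n_spikes(left) == 0L || n_spikes(right) == 0L) {
    stop("both spike trains must be non-empty", call. = FALSE)
  }
  r <- right$times
  cg <- vapply(line$taps, function(tau) {
    tl <- left$times + tau
    hi <- findInterval(tl + eps, r)
    lo <- findInterval(tl - eps, r, left.open = TRUE)
    sum(hi - lo)
  }, numeric(1))
  names(cg) <- format(line$taps)
  list(delay = line$taps[which.max(cg)], correlogram = cg)
}

#' Reverberatory short-term memory trajectory
#'
#' Circulates a spike pattern through a recurrent loop for `n_cycles`
#' cycles. The loop is pattern-preserving: event times are carried
#' unchanged modulo the loop delay, and only the pattern's scalar strength
#' evolves, as `strength[k] = min(saturation, gain^k)` with
#' `strength[0] = 1`.
#'
#' @param st A [spike_train()]: the circulating pattern.
#' @param loop A [recurrent_loop()].
#' @param n_cycles Number of loop traversals, >= 1.
#' @return A list of class `reverberation` with `strength` (length
#'   `n_cycles + 1`, cycles 0..n), `pattern` (the unchanged input train)
#'   and `loop`.
#' @export
reverberate <- function(st, loop, n_cycles) {
  stopifnot(inherits(st, "spike_train"), inherits(loop, "recurrent_loop"))
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  strength <- pmin(loop$saturation, loop$gain^(0:n_cycles))
  structure(list(strength = strength, pattern = st, loop = loop),
            class = "reverberation")
}

#' @export
print.reverberation <- function(x, ...) {
  cat(sprintf("<reverberation: %d cycles, gain %g, final strength %.5g>\n",
              length(x$strength) - 1L, x$loop$gain,
              x$strength[length(x$strength)]))
  invisible(x)
}

#' Coincidence-driven path facilitation
#'
#' Short-term, Hebbian-style facilitation of delay paths: each (tap,
#' input) path delays its input train by the tap and counts coincidence
#' events between the delayed input and the reference train
#' (`trains[[1]]`). The path's weight grows by
#' `learning_rate * count`, clipped to `[0, w_max]`; paths with no
#' coincidences are unchanged. There is no depression arm.
#'
#' @param pw A [path_weights()] whose column count equals
#'   `length(trains) - 1`.
#' @param trains List of spike trains; the first is the reference, the
#'   rest are the inputs, one per weight column.
#' @param det A [coincidence_detector()] (pairwise here, so its
#'   `min_count` should be 2).
#' @return The updated [path_weights()].
#' @export
facilitate_paths <- function(pw, trains, det = coincidence_detector()) {
  stopifnot(inherits(pw, "path_weights"))
  if (!is.list(trains) || length(trains) < 2L) {
    stop("need a reference train plus at least one input", call. = FALSE)
  }
  if (ncol(pw$weights) != length(trains) - 1L) {
    stop("weights have ", ncol(pw$weights), " input columns but ",
         length(trains) - 1L, " input trains were given", call. = FALSE)
  }
  ref <- trains[[1L]]
  for (i in seq_len(ncol(pw$weights))) {
    input <- trains[[i + 1L]]
    for (j in seq_along(pw$taps)) {
      delayed <- shift_train(input, pw$taps[j])
      cnt <- n_spikes(coincidence_detect(list(ref, delayed), det))
      if (cnt > 0L) {
        pw$weights[j, i] <- min(pw$w_max,
                                pw$weights[j, i] + pw$learning_rate * cnt)
      }
    }
  }
  pw
}
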