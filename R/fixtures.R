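#' Deterministic synthetic fixture generator
#'
#' Produces every input class the package's mechanisms assume, without any
#' external data: periodic and harmonic-complex waveforms, AM tones,
#' Poisson and jittered periodic spike trains, and random bipolar vectors.
#' Stochastic kinds require a seed and are bit-reproducible for a given
#' (spec, seed); the session RNG state is left untouched.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{`pure_tone`}{`freq` (Hz), optional `amplitude`, `phase`.}
#'   \item{`harmonic_complex`}{`freqs` (Hz vector), optional `amps`.}
#'   \item{`am_tone`}{`f_carrier`, `f_mod` (Hz), optional `depth` in
#'     `[0, 1]` (default 1). Envelope is the raised cosine
#'     `1 - depth/2 + depth/2 * (-cos(2 pi f_mod t))` scaled to `[1 -
#'     depth, 1]`.}
#'   \item{`poisson_train`}{`rate` (spikes/s); homogeneous Poisson
#'     process over `duration`. Requires `seed`.}
#'   \item{`jittered_periodic_train`}{`freq` (Hz), `jitter_sd` (s),
#'     optional `count` of independent trains (default 1; > 1 returns a
#'     list). Requires `seed`.}
#'   \item{`bipolar_vectors`}{`n` (dimension), `count`; random +-1/sqrt(n)
#'     vectors as a list. Requires `seed`.}
#' }
#'
#' @param kind One of the fixture kinds above.
#' @param parameters Named list of kind-specific parameters.
#' @param seed Integer seed; mandatory for stochastic kinds.
#' @param duration Duration in seconds (waveforms and spike trains).
#' @param sample_rate Sampling rate in Hz (waveform kinds; default 8000).
#' @return A [waveform()], a [spike_train()], a list of spike trains, or a
#'   list of numeric vectors, by kind.
#' @examples
#' w <- generate_fixture("harmonic_complex",
#'                       list(freqs = c(600, 800, 1000)), duration = 0.5)
#' @export
generate_fixture <- function(kind, parameters = list(), seed = NULL,
                             duration = 1, sample_rate = 8000) {
  kinds <- c("pure_tone", "harmonic_complex", "am_tone", "poisson_train",
             "jittered_periodic_train", "bipolar_vectors")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop("unknown fixture kind: ", deparse(kind), "; expected one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  stochastic <- kind %in% c("poisson_train", "jittered_periodic_train",
                            "bipolar_vectors")
  if (stochastic && is.null(seed)) {
    stop("field 'seed' is mandatory for stochastic kind '", kind, "'",
         call. = FALSE)
  }
  p <- parameters
  need <- function(field) {
    if (is.null(p[[field]])) {
      stop("kind '", kind, "' requires parameter field '", field, "'",
           call. = FALSE)
    }
    p[[field]]
  }
  gen <- function(expr) with_seed(seed, expr)
  switch(kind,
    pure_tone = {
      f <- need("freq")
      if (f <= 0) stop("field 'freq' must be > 0", call. = FALSE)
      sine_wave(f, duration, sample_rate,
                amplitude = p$amplitude %||% 1, phase = p$phase %||% 0)
    },
    harmonic_complex = {
      freqs <- need("freqs")
      if (any(freqs <= 0)) stop("field 'freqs' must be > 0", call. = FALSE)
      amps <- p$amps %||% rep(1, length(freqs))
      n <- round(duration * sample_rate)
      t <- (seq_len(n) - 1L) / sample_rate
      s <- numeric(n)
      for (i in seq_along(freqs)) s <- s + amps[i] * sin(2 * pi * freqs[i] * t)
      waveform(s, sample_rate)
    },
    am_tone = {
      fc <- need("f_carrier")
      fm <- need("f_mod")
      depth <- p$depth %||% 1
      if (depth < 0 || depth > 1) stop("field 'depth' must be in [0, 1]", call. = FALSE)
      n <- round(duration * sample_rate)
      t <- (seq_len(n) - 1L) / sample_rate
      env <- 1 - depth / 2 - depth / 2 * cos(2 * pi * fm * t)
      waveform(env * sin(2 * pi * fc * t), sample_rate)
    },
    poisson_train = {
      rate <- need("rate")
      if (rate <= 0) stop("field 'rate' must be > 0", call. = FALSE)
      gen({
        n <- stats::rpois(1L, rate * duration)
        spike_train(sort(stats::runif(n, 0, duration)), duration)
      })
    },
    jittered_periodic_train = {
      f <- need("freq")
      sd_j <- need("jitter_sd")
      count <- p$count %||% 1L
      gen({
        base <- seq(1 / f, duration, by = 1 / f)
        one <- function() {
          t <- base + stats::rnorm(length(base), 0, sd_j)
          t <- sort(t[t >= 0 & t <= duration])
          t <- t[c(TRUE, diff(t) > 0)]
          spike_train(t, duration)
        }
        if (count == 1L) one() else lapply(seq_len(count), function(i) one())
      })
    },
    bipolar_vectors = {
      n <- need("n")
      count <- need("count")
      gen(lapply(seq_len(count), function(i) {
        sample(c(-1, 1), n, replace = TRUE) / sqrt(n)
      }))
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so fixture generation never perturbs other randomness.
#' With `seed = NULL` the expression runs under the session RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
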