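# shared fixture helpers; all stochastic fixtures are seeded in the tests

make_tone <- function(freq, duration = 1, fs = 8000, amplitude = 1) {
  sine_wave(freq, duration, fs, amplitude = amplitude)
}

# independent oracle: cycle-by-cycle simulation of phase-locked spiking with
# a refractory period (event times on the exact period grid, greedy keep)
refractory_oracle <- function(freq, duration, refractory) {
  events <- seq(0, duration - 1e-12, by = 1 / freq)
  kept <- numeric(0)
  last <- -Inf
  for (t in events) {
    if (t - last >= refractory) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

cosine_sim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
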