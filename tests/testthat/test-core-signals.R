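test_that("waveform and spike_train enforce their invariants", {
  expect_error(waveform(numeric(0), 100), "at least one sample")
  expect_error(waveform(c(1, NaN), 100), "finite")
  expect_error(waveform(1:4, -1), "positive")
  expect_equal(duration(waveform(1:100, 50)), 2)

  expect_error(spike_train(c(0.2, 0.1)), "strictly increasing")
  expect_error(spike_train(c(0.1, 0.5), duration = 0.3), "duration")
  expect_equal(n_spikes(spike_train()), 0L)  # empty train is valid
})

test_that("zero-crossing encoding is phase-locked with interpolated times", {
  w <- make_tone(100, 1, 8000)
  st <- encode_phase_locked(w, "zero-crossing")
  expect_equal(n_spikes(st), 100)
  expect_equal(diff(st$times), rep(0.01, 99), tolerance = 1e-6)

  # sub-sample interpolation: crossings of a 100 Hz tone at a rate that is
  # not a multiple of 100 still land on the true period grid
  w2 <- sine_wave(100, 0.5, 8011)
  st2 <- encode_phase_locked(w2)
  expect_equal(max(abs(diff(st2$times) - 0.01)), 0, tolerance = 1e-5)

  expect_equal(n_spikes(encode_phase_locked(waveform(numeric(100), 1000))), 0L)
  expect_error(encode_phase_locked(w, threshold = Inf), "finite")
})

test_that("peak mode emits one spike per qualifying local maximum", {
  w <- make_tone(50, 0.5, 4000)
  st <- encode_phase_locked(w, "peak", threshold = 0.5)
  expect_equal(n_spikes(st), 25)
  expect_equal(diff(st$times), rep(0.02, 24), tolerance = 1e-6)
  # threshold above the peak amplitude suppresses everything
  expect_equal(n_spikes(encode_phase_locked(w, "peak", threshold = 1.5)), 0L)
})

test_that("refractory period matches the cycle-by-cycle oracle", {
  w <- make_tone(200, 1, 8000)
  st <- encode_phase_locked(w, refractory = 0.007)
  oracle <- refractory_oracle(200, 1, 0.007)
  expect_equal(n_spikes(st), length(oracle))
  expect_equal(st$times, oracle, tolerance = 1e-6)
  expect_equal(mean(diff(st$times)), 0.01, tolerance = 1e-6)
})

test_that("interval histograms count pairs per spec", {
  st <- spike_train(c(0, 0.010, 0.020))
  h <- interspike_intervals(st, "all", max_lag = 0.05, bin_width = 0.001)
  expect_equal(length(h$counts), 50L)
  expect_equal(h$counts[11L], 2L)  # 10 ms bin [0.010, 0.011)
  expect_equal(h$counts[21L], 1L)  # 20 ms
  expect_equal(sum(h$counts), 3L)

  hf <- interspike_intervals(st, "first", max_lag = 0.05, bin_width = 0.001)
  expect_equal(sum(hf$counts), 2L)
  expect_equal(hf$counts[11L], 2L)

  expect_equal(sum(interspike_intervals(spike_train(0.5), "all")$counts), 0L)
  expect_error(interspike_intervals(st, "all", max_lag = 0.001,
                                    bin_width = 0.002), "max_lag")
})

test_that("all-order counts respect the n(n-1)/2 bound and periodic support", {
  st <- spike_train(seq(0, 0.99, by = 0.01), 1)  # 100 Hz periodic, n = 100
  h <- interspike_intervals(st, "all", max_lag = 0.03, bin_width = 1e-4)
  n <- n_spikes(st)
  expect_lte(sum(h$counts), n * (n - 1) / 2)
  # support only at multiples of the period (to bin resolution)
  nz <- which(h$counts > 0)
  lag_bins <- histogram_lags(h)[nz]
  expect_true(all(abs(lag_bins / 0.01 - round(lag_bins / 0.01)) < 1e-6))
})

test_that("Poisson first-order intervals match the analytic exponential mean", {
  st <- generate_fixture("poisson_train", list(rate = 100), seed = 42,
                         duration = 100)
  h <- interspike_intervals(st, "first", max_lag = 0.2, bin_width = 1e-4)
  # empirical mean from the histogram (bin centers)
  centers <- histogram_lags(h) + h$bin_width / 2
  m <- sum(centers * h$counts) / sum(h$counts)
  expect_equal(m, 0.01, tolerance = 0.05)  # analytic mean 1/rate
})

test_that("population distribution is additive and permutation-invariant", {
  st <- spike_train(seq(0.005, 0.995, by = 0.005), 1)  # 200 Hz
  h1 <- interspike_intervals(st, "all")
  h2 <- population_interval_distribution(list(st, st), "all")
  expect_equal(h2$counts, 2L * h1$counts)
  expect_equal(h2$n_trains, 2L)

  trains <- generate_fixture("jittered_periodic_train",
                             list(freq = 137, jitter_sd = 3e-4, count = 4),
                             seed = 7)
  ha <- population_interval_distribution(trains, "all")
  hb <- population_interval_distribution(rev(trains), "all")
  expect_identical(ha$counts, hb$counts)

  empty <- list(spike_train(duration = 1), spike_train(duration = 1))
  expect_equal(sum(population_interval_distribution(empty, "all")$counts), 0L)
  expect_error(population_interval_distribution(list(), "all"), "non-empty")
})

test_that("jittered population histogram keeps modes at period multiples", {
  trains <- generate_fixture("jittered_periodic_train",
                             list(freq = 200, jitter_sd = 2e-4, count = 50),
                             seed = 11)
  h <- population_interval_distribution(trains, "all",
                                        max_lag = 0.02, bin_width = 1e-3)
  lags_ms <- histogram_lags(h) * 1e3
  # local modes of the binned distribution sit at the period multiples;
  # mass centered exactly on a half-open bin edge may split across the two
  # adjacent bins, so the mode is located to within one bin
  for (mode_ms in c(5, 10, 15)) {
    win <- which(abs(lags_ms - mode_ms) <= 2)
    peak_ms <- lags_ms[win][which.max(h$counts[win])]
    expect_lte(abs(peak_ms - mode_ms), 1)
  }
})

test_that("estimate_f0 recovers pure-tone F0 against the autocorrelation oracle", {
  for (f in c(50, 80, 123, 200, 313, 400)) {
    w <- make_tone(f, 0.5)
    h <- interspike_intervals(encode_phase_locked(w), "all")
    est <- estimate_f0(h, 40, 450)
    oracle <- autocorr_f0(w, 40, 450)
    expect_lt(abs(1 / est - 1 / oracle), h$bin_width + 1e-12)
  }
  # noiseless periodic train: exactly 100 Hz
  st <- spike_train(seq(0, 0.99, by = 0.01), 1)
  expect_equal(estimate_f0(interspike_intervals(st, "all"), 50, 400), 100)
  # no-estimate signals
  expect_true(is.na(estimate_f0(interspike_intervals(spike_train(), "all"),
                                50, 400)))
  expect_error(estimate_f0(interspike_intervals(st, "all"), 10, 20),
               "lag range")
})

test_that("missing fundamental is recovered across phase-locked channels", {
  w <- generate_fixture("harmonic_complex",
                        list(freqs = c(600, 800, 1000)),
                        duration = 0.5, sample_rate = 8000)
  trains <- phase_locked_channels(w, n_channels = 30)
  h <- population_interval_distribution(trains, "all")
  est <- estimate_f0(h, 50, 400)
  oracle <- autocorr_f0(w, 50, 400)
  expect_equal(est, 200, tolerance = 0.02)
  expect_lt(abs(1 / est - 1 / oracle), h$bin_width)
})
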