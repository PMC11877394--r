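test_that("mixing is pointwise multiplication with sum/difference sidebands", {
  fs <- 2000
  p <- mix(sine_wave(45, 10, fs), sine_wave(24, 10, fs))
  expect_equal(tone_component(p, 21)$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(tone_component(p, 69)$amplitude, 0.5, tolerance = 1e-6)

  # mixing with the constant 1 leaves the signal unchanged
  w <- sine_wave(45, 2, fs)
  ones <- waveform(rep(1, length(w$samples)), fs)
  expect_equal(mix(w, ones)$samples, w$samples)

  # F x F -> DC and 2F only
  p2 <- mix(w, w)
  expect_equal(mean(p2$samples), 0.5, tolerance = 1e-3)
  expect_equal(tone_component(p2, 90)$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(tone_component(p2, 45)$amplitude, 0, tolerance = 1e-6)

  expect_error(mix(w, sine_wave(45, 2, 1000)), "sample rate")
  expect_error(mix(w, sine_wave(45, 1, fs)), "length")
})

test_that("randomized F1/F2 grid shows exactly the two 0.5-amplitude sidebands", {
  set.seed(201)
  fs <- 2000
  for (rep in 1:8) {
    f1 <- runif(1, 5, 80)
    f2 <- runif(1, f1 + 5, 200)
    p <- mix(sine_wave(f2, 10, fs), sine_wave(f1, 10, fs))
    expect_equal(tone_component(p, f2 - f1)$amplitude, 0.5, tolerance = 1e-3)
    expect_equal(tone_component(p, f2 + f1)$amplitude, 0.5, tolerance = 1e-3)
    # nothing at the generating frequencies (small leakage from the finite,
    # non-integer-cycle window is all that remains)
    expect_lt(tone_component(p, f1)$amplitude, 0.01)
    expect_lt(tone_component(p, f2)$amplitude, 0.01)
  }
})

test_that("ssbcs_select keeps the difference band and abolishes the rest", {
  p <- mix(sine_wave(45, 20, 2000), sine_wave(24, 20, 2000))
  out <- ssbcs_select(p, mixer_stage(45, 24, lp_cutoff = 40))
  expect_equal(dominant_frequency(out, 5, 100), 21, tolerance = 0.1)
  res <- attr(out, "residual_db")
  expect_lt(res[["sum"]], -40)   # 69 Hz sum sideband
  expect_lt(res[["f1"]], -40)    # 24 Hz abolished
  expect_lt(res[["f2"]], -40)    # 45 Hz abolished

  # a product already below the cutoff passes through within ripple
  low <- mix(sine_wave(30, 20, 2000), sine_wave(25, 20, 2000))
  thru <- ssbcs_select(low, mixer_stage(30, 25, lp_cutoff = 20),
                       check = FALSE)
  expect_equal(tone_component(thru, 5)$amplitude, 0.5, tolerance = 5e-3)

  expect_error(mixer_stage(45, 24, lp_cutoff = 100), "strictly between")
  expect_error(mixer_stage(45, 45), "f_carrier > f_lo")
})

test_that("dominant_frequency finds, refines and refuses peaks", {
  w <- sine_wave(21, 10, 2000)
  expect_equal(dominant_frequency(w, 5, 100), 21, tolerance = 0.1)

  set.seed(202)
  noise <- waveform(rnorm(20000), 2000)
  expect_true(is.na(dominant_frequency(noise, 5, 100)))

  # two equal peaks: documented tie-break toward the lower frequency
  two <- superpose(list(component(sine_wave(30, 10, 2000)),
                        component(sine_wave(60, 10, 2000))))
  expect_equal(dominant_frequency(two, 5, 100), 30, tolerance = 0.1)

  expect_error(dominant_frequency(sine_wave(10, 0.2, 2000), 10, 50),
               "duration")
})

test_that("the seven-stage cascade reproduces the emergent carrier sequence", {
  res <- run_cascade(180, c(90, 45, 24, 10, 6, 2.5, 1.5), duration = 20)
  expect_equal(res$stages$emergent_hz, c(90, 45, 21, 11, 5, 2.5, 1),
               tolerance = 0.01)
  expect_equal(res$final_carrier, 1, tolerance = 0.1)
  # strictly frequency-decreasing
  expect_true(all(diff(res$stages$emergent_hz) < 0))
  # stage k+1 carrier is stage k's emergent carrier
  expect_equal(res$stages$f2[-1L], res$stages$emergent_hz[-7L])

  # suppression of distinguishable generating frequencies and all sums
  meas <- c(res$stages$residual_f1_db, res$stages$residual_f2_db,
            res$stages$sum_residual_db)
  expect_true(all(meas[!is.na(meas)] < -40))

  expect_error(run_cascade(180, c(90, 100)), "f_carrier > f_lo")
  expect_error(run_cascade(90, 90), "f_carrier > f_lo")
})

test_that("single-stage cascade: 180 Hz mixed with 90 Hz gives a 90 Hz carrier", {
  res <- run_cascade(180, 90, duration = 10)
  expect_equal(res$stages$emergent_hz, 90, tolerance = 0.1)
})

test_that("emergent carrier equals |F2 - F1| across a random stage grid", {
  set.seed(203)
  for (rep in 1:6) {
    f1 <- runif(1, 5, 60)
    f2 <- runif(1, f1 * 1.3 + 2, 180)
    res <- run_cascade(f2, f1, duration = 10)
    expect_equal(res$stages$emergent_hz, f2 - f1, tolerance = 0.1)
  }
})

test_that("envelopes ride the sidebands and survive a cascade stage", {
  fs <- 2000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  env <- waveform(0.5 - 0.5 * cos(2 * pi * 2 * t), fs)  # 2 Hz raised cosine

  m <- transport_envelope(env, 90)
  rec <- recover_envelope(m, 90)
  expect_gt(wf_correlate(rec, env), 0.95)

  # constant envelope recovers flat (to ripple)
  flat <- waveform(rep(0.7, length(t)), fs)
  rf <- recover_envelope(transport_envelope(flat, 90), 90)
  expect_equal(mean(rf$samples), 0.7, tolerance = 0.01)
  expect_lt(stats::sd(rf$samples), 0.02)

  # one SSBCS stage down (90 -> 45 Hz): envelope still recoverable
  lo <- waveform(sin(2 * pi * 45 * wf_times(m)), fs, t0 = m$t0)
  out <- ssbcs_select(mix(m, lo), mixer_stage(90, 45), check = FALSE)
  expect_gt(wf_correlate(recover_envelope(out, 45), env), 0.9)

  # bandwidth guard: envelope too fast for the carrier
  fast <- waveform(0.5 - 0.5 * cos(2 * pi * 50 * t), fs)
  expect_error(transport_envelope(fast, 90), "bandwidth")
})
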