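test_that("onset detection locates ideal, ramped and absent pulses correctly", {
  # instantaneous rise: onset at t0 within one sample
  tr <- make_ideal_trace(onset = 1)
  expect_lt(abs(detect_onset(tr) - 1), 0.002 + 1e-12)
  # finite 0.02 ms ramp with noise: within 0.01 ms of the generator onset
  cfg <- fixed_shot_config(seed = 4)
  cfg$noise_sd <- 0.1
  cfg$locations$upstream$rise <- 0.02
  g <- gen_shot_set(cfg)
  expect_lt(abs(detect_onset(correct_baseline(g$traces[["shot01_upstream"]])) - 1),
            0.01)
  # pure noise: no onset
  set.seed(8)
  noise <- pressure_trace(rnorm(2000, 0, 0.1), sample_rate = 5e5)
  expect_error(characterize_wave(noise), "no onset")
})

test_that("metrics on an ideal sampled pulse match the closed forms", {
  p <- friedlander_params(19.18, 1.99, 1, 1)
  wc <- characterize_wave(make_ideal_trace(19.18, 1.99, 1, onset = 1))
  expect_equal(wc$peak_magnitude, 19.18)
  expect_equal(wc$rise_time, 0)
  expect_lt(abs(wc$positive_duration - 1.99), 0.002)
  expect_lt(abs(wc$positive_impulse / quad_impulse(p) - 1), 1e-3)
  expect_error(characterize_wave(make_ideal_trace(window = 1.5)), "truncated")
})

test_that("impulse is robust to the sampling rate down to 50 kHz", {
  p <- friedlander_params(19.18, 1.99, 1, 1)
  for (fs in c(5e5, 2e5, 5e4)) {
    wc <- characterize_wave(make_ideal_trace(19.18, 1.99, 1, onset = 1, fs = fs))
    expect_lt(abs(wc$positive_impulse / quad_impulse(p) - 1), 0.005)
  }
})

test_that("synthetic upstream shots reproduce the characterized system's values", {
  cfg <- shot_config(n_shots = 20, seed = 31)
  g <- gen_shot_set(cfg)
  up <- g$traces[grepl("upstream", names(g$traces))]
  s <- summarize_shots(unname(lapply(up, function(x)
    characterize_wave(correct_baseline(x)))))
  expect_lt(abs(s$positive_duration_ms_mean - 1.99), 0.05)
  expect_lt(abs(s$peak_magnitude_psi_mean - 19.18), 1.24)
  expect_lt(abs(s$positive_impulse_psi_ms_mean - 14.03), 0.66)
})

test_that("percent difference is symmetric and matches direct evaluation", {
  expect_equal(percent_difference(7, 7), 0)
  expect_equal(percent_difference(59.93, 62.89),
               percent_difference(62.89, 59.93))
  # measured fixture peak vs value calculated from the adjacent overpressure
  expect_equal(percent_difference(59.93, reflected_pressure(20.88)),
               4.8, tolerance = 0.01)
  # inside the reported per-shot range
  expect_gt(percent_difference(59.93, reflected_pressure(20.88)), 0.7)
  expect_lt(percent_difference(59.93, reflected_pressure(20.88)), 14.3)
  expect_error(percent_difference(0, 1), "positive")
})

test_that("scaling pressure scales peak and impulse; shifting time moves only onset", {
  tr <- make_ideal_trace(19.18, 1.99, 1, onset = 1)
  wc <- characterize_wave(tr)
  for (k in c(0.5, 3)) {
    scaled <- tr
    scaled$pressure <- k * tr$pressure
    ws <- characterize_wave(scaled)
    expect_equal(ws$peak_magnitude, k * wc$peak_magnitude)
    expect_equal(ws$positive_impulse, k * wc$positive_impulse, tolerance = 1e-6)
    expect_equal(ws$rise_time, wc$rise_time)
    expect_equal(ws$positive_duration, wc$positive_duration)
  }
  shifted <- tr
  shifted$time <- tr$time + 2
  wt <- characterize_wave(shifted)
  expect_equal(wt$onset_time, wc$onset_time + 2)
  expect_equal(wt$peak_magnitude, wc$peak_magnitude)
  expect_equal(wt$positive_duration, wc$positive_duration)
  expect_equal(wt$positive_impulse, wc$positive_impulse)
})

test_that("Friedlander fit recovers exact parameters from a noiseless pulse", {
  f <- fit_friedlander(make_ideal_trace(19.18, 1.99, 1, onset = 1))
  expect_lt(abs(f$params$peak_overpressure / 19.18 - 1), 1e-3)
  expect_lt(abs(f$params$positive_duration / 1.99 - 1), 1e-3)
  expect_lt(abs(f$params$decay_constant - 1), 1e-3)
  expect_lt(f$rmse, 1e-6)
  expect_true(f$converged)
})

test_that("Friedlander fit recovers parameters under 2% noise across replicates", {
  cfg <- fixed_shot_config()
  cfg$noise_sd <- 0.02 * 19.18
  for (i in 1:20) {
    cfg$seed <- 400 + i
    g <- gen_shot_set(cfg)
    f <- fit_friedlander(correct_baseline(g$traces[["shot01_upstream"]]))
    expect_lt(abs(f$params$peak_overpressure / 19.18 - 1), 0.02)
    expect_lt(abs(f$params$positive_duration / 1.99 - 1), 0.02)
    expect_lt(abs(f$params$decay_constant - 1), 0.10)
  }
})

test_that("the impulse ratio of the upstream pulse solves to a decay constant near 1", {
  # bisection on the closed-form impulse shape I/(Pmax t+) for the
  # characterized upstream ratio 14.03 / (19.18 * 1.99)
  target <- 14.03 / (19.18 * 1.99)
  shape <- function(b)
    analytic_positive_impulse(friedlander_params(1, 1, b)) - target
  lo <- 0.01; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (shape(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 1.0, tolerance = 0.02)
})

test_that("shot summaries aggregate per location with sample SD", {
  tr <- make_ideal_trace()
  wc <- characterize_wave(tr)
  one <- summarize_shots(list(wc))
  expect_equal(one$n_shots, 1L)
  expect_equal(one$peak_magnitude_psi_mean, wc$peak_magnitude)
  expect_equal(one$peak_magnitude_psi_sd, 0)
  dup <- summarize_shots(list(wc, wc, wc))
  expect_equal(dup$n_shots, 3L)
  expect_equal(dup$peak_magnitude_psi_sd, 0)
  expect_error(summarize_shots(list()), "length")
})

test_that("summaries recover generator means within 3 standard errors", {
  cfg <- shot_config(n_shots = 100, noise_sd = 0.05, seed = 77)
  g <- gen_shot_set(cfg)
  chars <- lapply(g$traces, function(x) characterize_wave(correct_baseline(x)))
  s <- summarize_shots(unname(chars))
  up <- s[s$sensor_location == "upstream", ]
  se_peak <- 19.18 * 0.065 / sqrt(100)
  se_dur <- 1.99 * 0.015 / sqrt(100)
  expect_lt(abs(up$peak_magnitude_psi_mean - 19.18), 3 * se_peak)
  # generator positive duration includes the brief rise ramp
  expect_lt(abs(up$positive_duration_ms_mean - (1.99 + 0.019)), 3 * se_dur + 0.004)
})
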