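# shared oracles and fixture builders (all fixtures are generated in code)

# adaptive-quadrature oracle for the positive impulse, independent of the
# closed form under test
quad_impulse <- function(params) {
  stats::integrate(function(t) friedlander_pressure(params, t),
                   lower = params$onset_time,
                   upper = params$onset_time + params$positive_duration,
                   rel.tol = 1e-10)$value
}

# ideal sampled Friedlander pulse on a uniform grid (onset on-grid)
make_ideal_trace <- function(peak = 19.18, duration = 1.99, decay = 1,
                             onset = 1, fs = 5e5, window = NULL,
                             location = "upstream", shot_id = "shot01") {
  if (is.null(window)) window <- onset + 3 * duration
  t <- seq(0, window, by = 1000 / fs)
  p <- friedlander_params(peak, duration, decay, onset)
  pressure_trace(friedlander_pressure(p, t), time = t,
                 sensor_location = location, shot_id = shot_id)
}

# single-shot generator config with all shot-to-shot variation removed
fixed_shot_config <- function(...) {
  cfg <- shot_config(n_shots = 1L, noise_sd = 0,
                     baseline_offset_range = c(0, 0),
                     ripple = list(amplitude_fraction = 0, frequency_khz = 5,
                                   decay_ms = 0.5), ...)
  cfg$locations <- lapply(cfg$locations, function(L) {
    L$cv_peak <- 0; L$cv_duration <- 0; L
  })
  cfg
}

# paint a filled disk into a logical matrix
paint_disk <- function(mask, cx, cy, r) {
  d2 <- outer((seq_len(nrow(mask)) - cx)^2, (seq_len(ncol(mask)) - cy)^2, "+")
  mask | d2 <= r^2
}
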