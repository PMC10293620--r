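#' Detect wave arrival time
#'
#' Finds the first sample exceeding `threshold_fraction` of the peak, then
#' walks back to the preceding noise-level crossing, so that a finite rise
#' ramp is credited to the pulse rather than truncated at the threshold.
#' The noise level is three standard deviations of the pre-trigger baseline
#' (first 10% of samples).
#'
#' @param trace A conditioned [pressure_trace()].
#' @param threshold_fraction Detection threshold as a fraction of the peak.
#'   Default 0.05, robust to reflection-contaminated (noisy) sensors.
#'
#' @return Onset time t0 in ms (invisibly also available via
#'   [characterize_wave()]).
#' @export
detect_onset <- function(trace, threshold_fraction = 0.05) {
  stopifnot(inherits(trace, "pressure_trace"),
            threshold_fraction > 0, threshold_fraction < 1)
  idx <- .onset_index(trace, threshold_fraction)
  trace$time[idx]
}

# onset as an index; shared by detect_onset and characterize_wave
.onset_index <- function(trace, threshold_fraction = 0.05) {
  p <- trace$pressure
  n <- length(p)
  base <- p[seq_len(max(2L, floor(0.1 * n)))]
  noise_level <- max(3 * stats::sd(base), 1e-9 * max(abs(p)), 1e-12)
  peak <- max(p)
  if (peak <= 2 * noise_level)
    stop("no onset: peak (", signif(peak, 3), " psi) is below the noise floor")
  # walk back from the peak to the threshold crossing (robust to baseline
  # noise spikes), then on to the preceding noise-level crossing
  i <- which.max(p)
  thr <- threshold_fraction * peak
  while (i > 1L && p[i - 1L] > thr) i <- i - 1L
  while (i > 1L && p[i - 1L] > noise_level) i <- i - 1L
  i
}

#' Characterize a pressure pulse
#'
#' Extracts the standard positive-phase metrics of a single blast pulse:
#' peak magnitude (maximum pressure), rise time (onset to peak), positive
#' duration (onset to the first linearly interpolated zero down-crossing
#' after the peak), and positive impulse (trapezoidal area under the curve
#' from onset to that zero crossing).
#'
#' @param trace A conditioned [pressure_trace()].
#' @param threshold_fraction Onset detection threshold; see [detect_onset()].
#'
#' @return An object of class `wave_characteristics`: a list with
#'   `peak_magnitude` (psi), `rise_time` (ms), `positive_duration` (ms),
#'   `positive_impulse` (psi*ms), `onset_time` (ms), and the trace's
#'   `sensor_location` and `shot_id`.
#' @export
characterize_wave <- function(trace, threshold_fraction = 0.05) {
  stopifnot(inherits(trace, "pressure_trace"))
  i0 <- .onset_index(trace, threshold_fraction)
  t <- trace$time
  p <- trace$pressure
  n <- length(p)
  i_peak <- which.max(p)
  if (i_peak < i0) stop("peak precedes detected onset; trace not conditioned?")
  after <- seq.int(i_peak, n)
  if (!any(p[after] < 0))
    stop("truncated pulse: no zero down-crossing after the peak")
  noise_sd <- stats::sd(p[seq_len(max(2L, floor(0.1 * n)))])
  if (noise_sd <= 1e-4 * p[i_peak]) {
    # clean trace: linearly interpolated crossing at the first sign change
    k <- after[which(p[after] < 0)[1L]]
    t_zero <- t[k - 1L] + (t[k] - t[k - 1L]) * p[k - 1L] / (p[k - 1L] - p[k])
  } else {
    # noisy trace: the first negative raw sample is systematically early, so
    # take a provisional crossing from a centred moving average (detection
    # only; the analyzed samples stay unfiltered) and refine it by local
    # linear regression on the raw samples around it
    q <- stats::filter(p[after], rep(1 / 25, 25), sides = 2)
    q[is.na(q)] <- p[after][is.na(q)]
    k_rel <- which(q < 0)[1L]
    if (is.na(k_rel)) k_rel <- which(p[after] < 0)[1L]
    k <- after[k_rel]
    win <- seq.int(max(i_peak + 1L, k - 40L), min(n, k + 40L))
    cf <- stats::lm.fit(cbind(1, t[win]), p[win])$coefficients
    t_zero <- if (is.finite(cf[2L]) && cf[2L] < 0) -cf[1L] / cf[2L] else NA_real_
    if (!is.finite(t_zero) || t_zero <= t[i_peak] ||
        abs(t_zero - t[k]) > 60 * (t[2L] - t[1L]))
      t_zero <- t[k - 1L] + (t[k] - t[k - 1L]) * p[k - 1L] / (p[k - 1L] - p[k])
    t_zero <- min(max(t_zero, t[i_peak]), t[n])
  }
  j <- min(max(findInterval(t_zero, t), i_peak), n)  # last sample <= t_zero
  idx <- seq.int(i0, j)
  impulse <- sum(diff(t[idx]) * (p[idx[-length(idx)]] + p[idx[-1L]]) / 2) +
    p[j] * (t_zero - t[j]) / 2
  structure(list(peak_magnitude = p[i_peak],
                 rise_time = t[i_peak] - t[i0],
                 positive_duration = t_zero - t[i0],
                 positive_impulse = impulse,
                 onset_time = t[i0],
                 sensor_location = trace$sensor_location,
                 shot_id = trace$shot_id),
            class = "wave_characteristics")
}

#' @export
print.wave_characteristics <- function(x, ...) {
  cat(sprintf(
    "<wave_characteristics> shot %s (%s): peak %.2f psi, rise %.3f ms, t+ %.3f ms, impulse %.2f psi*ms\n",
    x$shot_id, x$sensor_location, x$peak_magnitude, x$rise_time,
    x$positive_duration, x$positive_impulse))
  invisible(x)
}

#' Symmetric percent difference
#'
#' `200 * |a - b| / (a + b)`: the absolute difference relative to the mean
#' of the two values, in percent. Symmetric in its arguments, so no choice
#' of reference value is implied. Used to compare measured reflected
#' pressures against values calculated from the static overpressure.
#'
#' @param a,b Positive values (psi, or any common unit); vectorized.
#'
#' @return Percent difference(s).
#' @export
#' @examples
#' percent_difference(59.93, 62.89)  # ~4.8%
percent_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(a <= 0) || any(b <= 0))
    stop("percent difference requires positive inputs")
  200 * abs(a - b) / (a + b)
}

#' Fit Friedlander parameters to a pulse
#'
#' Nonlinear least squares of the modified Friedlander form to a measured
#' pulse, initialized from [characterize_wave()] with decay constant 1 and
#' fitted over the window from onset to `window_factor` times the measured
#' positive duration.
#'
#' On its positive support the modified Friedlander model
#' `Pmax (1 - u) exp(-b u)`, `u = (t - t0)/t+`, reparameterizes as
#' `A (c - t) exp(-beta t)` — three functional degrees of freedom, so a
#' free onset time makes the least-squares Jacobian exactly rank-deficient.
#' The fit therefore proceeds in two identifiable steps: (1) the decay
#' curve `A (c - t) exp(-beta t)` is fitted from the measured peak onward;
#' (2) the model clock is placed where the rising edge meets the fitted
#' decay — the intersection of a least-squares line through the rise-ramp
#' samples with the fitted curve (or the detected onset itself when the
#' rise is unresolved, as for an ideal instantaneous-rise pulse). The
#' reported `(Pmax, t+, b)` are the fitted curve's value, remaining
#' duration and decay constant at that point, and `onset_time` is that
#' point, so the returned parameter set reproduces the fitted curve
#' through [friedlander_pressure()].
#'
#' @param trace A conditioned [pressure_trace()].
#' @param window_factor Fitted window length as a multiple of the measured
#'   positive duration. Default 1.5 so the early underpressure constrains
#'   the decay constant.
#'
#' @return A list with `params` (a [friedlander_params()], onset at the
#'   detected onset), `rmse` (psi, on the fitted window) and `converged`
#'   (logical).
#' @export
fit_friedlander <- function(trace, window_factor = 1.5) {
  stopifnot(inherits(trace, "pressure_trace"), window_factor > 0)
  wc <- characterize_wave(trace)
  t <- trace$time
  p <- trace$pressure
  i_max <- which.max(p)
  a <- t[i_max]                           # provisional anchor: raw peak time
  sel <- t >= a & t <= a + window_factor * wc$positive_duration
  tau <- t[sel] - a
  pp <- p[sel]
  tp0 <- max(wc$positive_duration - wc$rise_time, 1e-6)
  fit <- try(minpack.lm::nlsLM(
    pp ~ Pmax * (1 - tau / tp) * exp(-b * tau / tp),
    start = list(Pmax = wc$peak_magnitude, tp = tp0, b = 1),
    lower = c(Pmax = 1e-9, tp = 1e-9, b = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Friedlander fit did not converge: ", attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  curve <- function(x)                    # fitted decay, any anchor
    cf[["Pmax"]] * (1 - (x - a) / cf[["tp"]]) * exp(-cf[["b"]] * (x - a) / cf[["tp"]])

  # place the model clock where the rising edge meets the fitted decay
  i0 <- .onset_index(trace)
  rise_idx <- seq.int(i0, i_max)
  rise_idx <- rise_idx[p[rise_idx] >= 0.15 * wc$peak_magnitude &
                         p[rise_idx] <= 0.85 * wc$peak_magnitude]
  t_ref <- wc$onset_time + wc$rise_time   # fallback: measured peak time
  if (length(rise_idx) >= 2L) {
    line <- stats::lm.fit(cbind(1, t[rise_idx]), p[rise_idx])$coefficients
    if (is.finite(line[2L]) && line[2L] > 0) {
      g <- function(x) line[1L] + line[2L] * x - curve(x)
      root <- try(stats::uniroot(g, lower = t[i0], upper = a + cf[["tp"]] / 2,
                                 extendInt = "upX"), silent = TRUE)
      if (!inherits(root, "try-error")) t_ref <- root$root
    }
  } else if (wc$rise_time <= 2 * (t[2L] - t[1L])) {
    t_ref <- wc$onset_time                # unresolved rise: ideal pulse
  }
  tp <- cf[["tp"]] - (t_ref - a)
  b <- cf[["b"]] * tp / cf[["tp"]]
  list(params = friedlander_params(curve(t_ref), tp, b, t_ref),
       rmse = sqrt(mean(stats::resid(fit)^2)),
       converged = TRUE)
}

#' Cross-shot repeatability summary
#'
#' Aggregates per-pulse metrics by sensor location into the standard
#' repeatability table: mean and sample (n-1) standard deviation of the
#' positive duration, rise time, peak magnitude and positive impulse,
#' with the number of shots per location.
#'
#' @param chars A list of `wave_characteristics` objects from
#'   [characterize_wave()].
#'
#' @return A tibble with one row per sensor location (ordered upstream,
#'   adjacent, fixture) and columns `<metric>_<unit>_mean` / `_sd` plus
#'   `n_shots`. Locations with a single shot get sd 0 and are flagged via
#'   `n_shots = 1`.
#' @export
summarize_shots <- function(chars) {
  stopifnot(is.list(chars), length(chars) >= 1L,
            all(vapply(chars, inherits, logical(1), "wave_characteristics")))
  df <- tibble::tibble(
    sensor_location = vapply(chars, `[[`, character(1), "sensor_location"),
    positive_duration_ms = vapply(chars, `[[`, numeric(1), "positive_duration"),
    rise_time_ms = vapply(chars, `[[`, numeric(1), "rise_time"),
    peak_magnitude_psi = vapply(chars, `[[`, numeric(1), "peak_magnitude"),
    positive_impulse_psi_ms = vapply(chars, `[[`, numeric(1), "positive_impulse"))
  locs <- intersect(c("upstream", "adjacent", "fixture"),
                    unique(df$sensor_location))
  rows <- lapply(locs, function(loc) {
    d <- df[df$sensor_location == loc, ]
    out <- tibble::tibble(sensor_location = loc, n_shots = nrow(d))
    for (m in c("positive_duration_ms", "rise_time_ms",
                "peak_magnitude_psi", "positive_impulse_psi_ms")) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(d) > 1L) stats::sd(d[[m]]) else 0
    }
    out
  })
  do.call(rbind, rows)
}
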