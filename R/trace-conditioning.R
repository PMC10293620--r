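#' Construct a pressure trace
#'
#' One sensor's uniformly sampled time/pressure series for one shot.
#' Time is in ms, pressure in psi; shock-tube acquisition is nominally
#' 500 kHz.
#'
#' @param pressure Numeric vector of pressures (psi), length >= 2, finite.
#' @param time Optional numeric vector of times (ms), strictly increasing on
#'   a uniform grid. Derived from `sample_rate` (starting at 0) when absent.
#' @param sample_rate Sampling rate in Hz. Default 500000.
#' @param sensor_location One of `"upstream"`, `"adjacent"`, `"fixture"`.
#' @param shot_id Label identifying the shot.
#'
#' @return An object of class `pressure_trace`: a list with elements `time`,
#'   `pressure`, `sample_rate`, `sensor_location`, `shot_id`.
#' @export
pressure_trace <- function(pressure, time = NULL, sample_rate = 5e5,
                           sensor_location = c("upstream", "adjacent", "fixture"),
                           shot_id = "shot") {
  sensor_location <- match.arg(sensor_location)
  stopifnot(is.numeric(pressure), length(pressure) >= 2L)
  if (any(!is.finite(pressure))) stop("`pressure` must be finite")
  if (is.null(time)) {
    time <- (seq_along(pressure) - 1L) * 1000 / sample_rate
  } else {
    stopifnot(is.numeric(time), length(time) == length(pressure))
    dt <- diff(time)
    if (any(dt <= 0)) stop("`time` must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * mean(dt) * length(dt))
      stop("`time` must be a uniform grid")
    sample_rate <- 1000 / mean(dt)
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 sample_rate = sample_rate, sensor_location = sensor_location,
                 shot_id = as.character(shot_id)),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> shot %s, %s sensor: %d samples @ %.0f kHz, peak %.2f psi\n",
              x$shot_id, x$sensor_location, length(x$pressure),
              x$sample_rate / 1000, max(x$pressure)))
  invisible(x)
}

# contiguous run of positive pressure containing the global maximum
.positive_phase_idx <- function(pressure) {
  i_peak <- which.max(pressure)
  pos <- pressure > 0
  lo <- i_peak
  while (lo > 1L && pos[lo - 1L]) lo <- lo - 1L
  hi <- i_peak
  n <- length(pressure)
  while (hi < n && pos[hi + 1L]) hi <- hi + 1L
  lo:hi
}

#' Correct a baseline offset
#'
#' Subtracts the mean of a pre-trigger segment so that the quiescent
#' baseline sits at zero. This is a constant subtraction only; the waveform
#' shape is untouched (no filtering is ever applied to pressure traces).
#'
#' @param trace A [pressure_trace()].
#' @param pretrigger_window Length of the pre-trigger segment in ms, taken
#'   from the start of the trace. Default `NULL` uses the first 10% of
#'   samples, which must lie before wave arrival.
#'
#' @return A baseline-corrected `pressure_trace`.
#' @export
correct_baseline <- function(trace, pretrigger_window = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  n <- length(trace$pressure)
  if (is.null(pretrigger_window)) {
    n_pre <- max(2L, floor(0.1 * n))
  } else {
    stopifnot(is.numeric(pretrigger_window), pretrigger_window > 0)
    if (pretrigger_window >= diff(range(trace$time)))
      stop("`pretrigger_window` (", pretrigger_window,
           " ms) is longer than the trace")
    n_pre <- sum(trace$time - trace$time[1L] < pretrigger_window)
    n_pre <- max(2L, n_pre)
  }
  trace$pressure <- trace$pressure - mean(trace$pressure[seq_len(n_pre)])
  trace
}

# least-squares polynomial extrapolation from a flank of samples;
# returns NULL when fewer than 2 usable points
.flank_fit <- function(t, p, at) {
  if (length(t) < 2L) return(NULL)
  deg <- min(2L, length(t) - 1L)
  # centre time for conditioning
  t0 <- mean(t)
  fit <- stats::lm.fit(outer(t - t0, 0:deg, "^"), p)
  drop(outer(at - t0, 0:deg, "^") %*% fit$coefficients)
}

#' Detect and repair sensor clipping
#'
#' Saturated (clipped) samples are detected as runs of at least `min_run`
#' consecutive samples within 0.1% of the saturation level (the trace
#' maximum when no level is configured). Each clipped span is repaired by
#' two-sided envelope extrapolation: low-order polynomials are fit by least
#' squares to the rising flank and to the decaying flank, and the repaired
#' value is the pointwise minimum of the two extrapolations, floored at the
#' saturation level. For a pulse whose crest was flattened, the two
#' envelopes intersect near the true peak, so the peak magnitude is
#' recovered rather than capped at the saturation ceiling.
#'
#' A trace is flagged severe when the clipped samples exceed
#' `severe_fraction` of the positive-phase samples, or when a clipped span
#' touches the trace boundary (no flanking samples to extrapolate from, so
#' no repair is attempted). Severely clipped traces are meant to be excluded
#' from analysis via [exclude_traces()].
#'
#' @param trace A [pressure_trace()] (baseline-corrected).
#' @param saturation_level Known saturation level in psi; default `NULL`
#'   uses the trace maximum.
#' @param min_run Minimum run length (samples) for a clipped span. Default 3.
#' @param severe_fraction Fraction of positive-phase samples above which
#'   clipping is severe. Default 0.25.
#' @param n_flank Samples per flank used for envelope extrapolation.
#'   Default `NULL` sizes each flank to twice the clipped span (at least
#'   25 samples), so the extrapolation is supported by a window comparable
#'   to the gap it bridges.
#'
#' @return A list with elements `trace` (repaired, or the input when clean
#'   or unrepairable) and `report`, an object of class `clipping_report`
#'   with fields `clipped`, `clipped_spans` (list of `c(start, end)` index
#'   pairs), `severe`, `repaired`, plus the shot id and sensor location.
#' @export
detect_and_repair_clipping <- function(trace, saturation_level = NULL,
                                       min_run = 3L, severe_fraction = 0.25,
                                       n_flank = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (!is.null(saturation_level) && saturation_level <= 0)
    stop("`saturation_level` must be > 0 psi")
  p <- trace$pressure
  n <- length(p)
  level <- if (is.null(saturation_level)) max(p) else saturation_level
  at_level <- abs(p - level) <= 1e-3 * abs(level)

  r <- rle(at_level)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  spans <- Map(c, starts[keep], ends[keep])

  report <- structure(
    list(clipped = length(spans) > 0L, clipped_spans = spans,
         severe = FALSE, repaired = FALSE,
         shot_id = trace$shot_id, sensor_location = trace$sensor_location),
    class = "clipping_report")
  if (length(spans) == 0L) return(list(trace = trace, report = report))

  boundary <- any(vapply(spans, function(s) s[1L] == 1L || s[2L] == n, logical(1)))
  n_clipped <- sum(vapply(spans, function(s) s[2L] - s[1L] + 1L, integer(1)))
  n_pos <- length(.positive_phase_idx(p))
  report$severe <- boundary || n_clipped > severe_fraction * n_pos
  if (boundary) return(list(trace = trace, report = report))

  noise_floor <- 0.05 * level
  for (s in spans) {
    nf <- if (is.null(n_flank)) max(25L, 2L * (s[2L] - s[1L] + 1L)) else n_flank
    li <- seq.int(max(1L, s[1L] - nf), s[1L] - 1L)
    li <- li[p[li] > noise_floor]            # keep the rising flank only
    ri <- seq.int(s[2L] + 1L, min(n, s[2L] + nf))
    ri <- ri[p[ri] > noise_floor]
    at <- trace$time[s[1L]:s[2L]]
    left <- .flank_fit(trace$time[li], p[li], at)
    right <- .flank_fit(trace$time[ri], p[ri], at)
    val <- if (is.null(left)) right else if (is.null(right)) left else pmin(left, right)
    if (is.null(val)) { report$severe <- TRUE; return(list(trace = trace, report = report)) }
    p[s[1L]:s[2L]] <- pmax(val, level)
  }
  trace$pressure <- p
  report$repaired <- TRUE
  list(trace = trace, report = report)
}

#' Exclude severely clipped shots
#'
#' A shot is excluded when any of its analyzed sensors reports severe
#' clipping, mirroring the removal of unusable traces from repeatability
#' analysis.
#'
#' @param reports A list of `clipping_report` objects (one per shot/sensor),
#'   as returned by [detect_and_repair_clipping()].
#'
#' @return A list with `kept` (character vector of shot ids) and `excluded`
#'   (tibble with `shot_id`, `sensor_location`, `reason`).
#' @export
exclude_traces <- function(reports) {
  stopifnot(is.list(reports),
            all(vapply(reports, inherits, logical(1), "clipping_report")))
  shot <- vapply(reports, `[[`, character(1), "shot_id")
  loc <- vapply(reports, `[[`, character(1), "sensor_location")
  severe <- vapply(reports, `[[`, logical(1), "severe")
  bad <- unique(shot[severe])
  kept <- setdiff(unique(shot), bad)
  if (length(kept) == 0L && length(bad) > 0L)
    warning("all shots excluded due to severe clipping")
  excluded <- tibble::tibble(
    shot_id = shot[severe], sensor_location = loc[severe],
    reason = "severe clipping")
  list(kept = kept, excluded = excluded)
}
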