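#' Open-field arena geometry
#'
#' Square arena with a concentric center zone (for anxiety-like center
#' occupancy) and a wall zone (for thigmotaxis / wall-visit counting).
#'
#' @param side_length Arena side in cm. Default 80.
#' @param center_zone_fraction Side of the center square as a fraction of
#'   the arena side (0.5 gives an inner square covering 25% of the area,
#'   the common open-field convention). Default 0.5.
#' @param wall_margin Width of the wall zone in cm. Default 10.
#'
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(side_length = 80, center_zone_fraction = 0.5,
                       wall_margin = 10) {
  stopifnot(side_length > 0,
            center_zone_fraction > 0, center_zone_fraction < 1,
            wall_margin > 0, wall_margin < side_length / 2)
  structure(list(side_length = side_length,
                 center_zone_fraction = center_zone_fraction,
                 wall_margin = wall_margin),
            class = "arena_spec")
}

#' Tracked open-field trajectory
#'
#' Wraps a three-point tracking table (nose, body center, tail base) at a
#' fixed frame rate, as exported by video-tracking software.
#'
#' @param frames A data frame with columns `t` (s, non-decreasing), `point`
#'   (`"nose"`, `"center"`, `"tail"`), `x`, `y` (cm). `NA` coordinates mark
#'   lost frames.
#' @param frame_rate Frames per second. Default 30.
#'
#' @return An object of class `oft_trajectory` (a tibble with attributes).
#' @export
oft_trajectory <- function(frames, frame_rate = 30) {
  stopifnot(is.data.frame(frames),
            all(c("t", "point", "x", "y") %in% names(frames)),
            frame_rate > 0)
  if (is.unsorted(frames$t)) stop("`t` must be non-decreasing")
  bad <- !frames$point %in% c("nose", "center", "tail")
  if (any(bad)) stop("unknown tracked point(s): ",
                     paste(unique(frames$point[bad]), collapse = ", "))
  out <- tibble::as_tibble(frames)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("oft_trajectory", class(out))
  out
}

# one tracked point's frames, with gaps up to max_gap frames linearly
# interpolated; longer gaps left as NA (they split the session)
.point_frames <- function(traj, point, max_gap = 5L) {
  stopifnot(inherits(traj, "oft_trajectory"))
  d <- traj[traj$point == point, , drop = FALSE]
  if (nrow(d) < 2L) stop("need >= 2 frames of point '", point, "'")
  for (col in c("x", "y")) {
    v <- d[[col]]
    if (anyNA(v) && sum(!is.na(v)) >= 2L) {
      filled <- stats::approx(d$t[!is.na(v)], v[!is.na(v)], xout = d$t,
                              rule = 1)$y
      gap_len <- .gap_lengths(is.na(v))
      v[is.na(v) & gap_len <= max_gap] <-
        filled[is.na(v) & gap_len <= max_gap]
      d[[col]] <- v
    }
  }
  d
}

# for each position, length of the NA run it belongs to (0 if not NA)
.gap_lengths <- function(na) {
  r <- rle(na)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

#' Total distance traveled
#'
#' Sum of Euclidean step lengths between consecutive frames of one tracked
#' point (the body center by default). Steps across unresolvable tracking
#' gaps are dropped.
#'
#' @param traj An [oft_trajectory()].
#' @param point Tracked point to use. Default `"center"`.
#'
#' @return Distance in cm.
#' @export
total_distance <- function(traj, point = "center") {
  d <- .point_frames(traj, point)
  steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  sum(steps, na.rm = TRUE)
}

#' Maximum and mean velocity
#'
#' Per-frame speed is the step length times the frame rate, optionally
#' smoothed with a centred moving average before taking the maximum (a
#' window of 1, the default, applies no smoothing). Steps across
#' unresolvable tracking gaps are excluded.
#'
#' @param traj An [oft_trajectory()].
#' @param point Tracked point. Default `"center"`.
#' @param smoothing_window Moving-average window in frames. Default 1.
#'
#' @return A list with `max_velocity` and `mean_velocity` in cm/s.
#' @export
velocity_metrics <- function(traj, point = "center", smoothing_window = 1L) {
  stopifnot(smoothing_window >= 1L)
  d <- .point_frames(traj, point)
  fps <- attr(traj, "frame_rate")
  speed <- sqrt(diff(d$x)^2 + diff(d$y)^2) * fps
  speed <- speed[is.finite(speed)]
  if (length(speed) == 0L) return(list(max_velocity = 0, mean_velocity = 0))
  if (smoothing_window > 1L)
    speed <- stats::filter(speed, rep(1 / smoothing_window, smoothing_window),
                           sides = 2)
  speed <- speed[is.finite(speed)]
  list(max_velocity = max(speed), mean_velocity = mean(speed))
}

# per-frame logical zone membership for the body-center point
.in_center <- function(x, y, arena) {
  half <- arena$side_length / 2
  r <- arena$center_zone_fraction * arena$side_length / 2
  abs(x - half) <= r & abs(y - half) <= r
}

.in_wall_zone <- function(x, y, arena) {
  s <- arena$side_length
  m <- arena$wall_margin
  x <= m | x >= s - m | y <= m | y >= s - m
}

#' Time spent in the arena center
#'
#' Dwell time of the body-center point inside the concentric center square;
#' frames on the zone boundary count as inside. Each frame contributes one
#' frame period of dwell time. Reduced center occupancy (thigmotaxis) is the
#' standard open-field indicator of anxiety-like behavior.
#'
#' @param traj An [oft_trajectory()].
#' @param arena An [arena_spec()].
#'
#' @return A list with `center_time` (s) and `center_fraction` (of resolved
#'   frames).
#' @export
center_time <- function(traj, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  d <- .point_frames(traj, "center")
  ok <- is.finite(d$x) & is.finite(d$y)
  inside <- .in_center(d$x[ok], d$y[ok], arena)
  fps <- attr(traj, "frame_rate")
  list(center_time = sum(inside) / fps,
       center_fraction = mean(inside))
}

#' Wall-visit frequency
#'
#' Number of entries of the body-center point into the wall zone (within
#' `wall_margin` of any wall), an entry being an outside-to-inside zone
#' transition between consecutive resolved frames.
#'
#' @param traj An [oft_trajectory()].
#' @param arena An [arena_spec()].
#'
#' @return Integer entry count.
#' @export
wall_visit_count <- function(traj, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  d <- .point_frames(traj, "center")
  ok <- is.finite(d$x) & is.finite(d$y)
  inside <- .in_wall_zone(d$x[ok], d$y[ok], arena)
  if (length(inside) < 2L) return(0L)
  sum(!inside[-length(inside)] & inside[-1L])
}

#' Compute all open-field metrics for one session
#'
#' @param traj An [oft_trajectory()].
#' @param arena An [arena_spec()].
#' @param point Tracked point for distance/velocity. Default `"center"`.
#' @param smoothing_window Velocity smoothing window in frames. Default 1.
#'
#' @return A one-row tibble with `total_distance_cm`, `max_velocity_cm_s`,
#'   `mean_velocity_cm_s`, `center_time_s`, `center_fraction`,
#'   `wall_visit_count`.
#' @export
oft_metrics <- function(traj, arena, point = "center", smoothing_window = 1L) {
  v <- velocity_metrics(traj, point, smoothing_window)
  ct <- center_time(traj, arena)
  tibble::tibble(
    total_distance_cm = total_distance(traj, point),
    max_velocity_cm_s = v$max_velocity,
    mean_velocity_cm_s = v$mean_velocity,
    center_time_s = ct$center_time,
    center_fraction = ct$center_fraction,
    wall_visit_count = wall_visit_count(traj, arena))
}

#' Validate Tarlov motor scores
#'
#' Tarlov scores are integers from 0 (full paralysis) to 5 (normal
#' locomotion). Out-of-range or non-integer entries raise an error naming
#' the offending subject and day.
#'
#' @param scores A data frame with columns `subject_id`, `day`, `score`
#'   (and optionally `group`).
#'
#' @return A list with `scores` (validated tibble), `summary` (median score
#'   per day, per group when a `group` column is present) and `all_normal`
#'   (TRUE when every score is 5, i.e. normal locomotion throughout).
#' @export
validate_tarlov <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("subject_id", "day", "score") %in% names(scores)))
  s <- scores$score
  bad <- !is.finite(s) | s != round(s) | s < 0 | s > 5
  if (any(bad)) {
    ctx <- paste0(scores$subject_id[bad], " day ", scores$day[bad],
                  " (score ", s[bad], ")")
    stop("invalid Tarlov score(s), must be integers in 0..5: ",
         paste(utils::head(ctx, 5L), collapse = "; "))
  }
  scores <- tibble::as_tibble(scores)
  by <- if ("group" %in% names(scores)) {
    list(group = scores$group, day = scores$day)
  } else {
    list(day = scores$day)
  }
  summary <- stats::aggregate(list(median_score = scores$score), by, stats::median)
  list(scores = scores, summary = tibble::as_tibble(summary),
       all_normal = all(scores$score == 5L))
}
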