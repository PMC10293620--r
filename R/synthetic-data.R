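#' Shot-set generator configuration
#'
#' Defaults emulate the characterized shock-tube conditions: an upstream
#' static overpressure following a clean Friedlander waveform (19.18 psi
#' peak, 1.99 ms positive phase, decay constant 1), a shorter, rippled
#' pulse adjacent to the animal fixture (20.88 psi, 1.56 ms) whose
#' post-peak reflections are modeled as a damped sinusoid, and a fixture
#' reflected-pressure sensor whose peak is tied to the adjacent static
#' overpressure through the normal-reflection relation (with multiplicative
#' shot-to-shot noise). Coefficients of variation come from the
#' repeatability table of the characterized system.
#'
#' @param n_shots Number of shots. Default 7.
#' @param locations Named list (upstream/adjacent/fixture), each a list with
#'   `peak` (psi), `duration` (ms), `decay` (dimensionless), `rise` (ms),
#'   `cv_peak`, `cv_duration`. Fixture `peak = NA` means "tie to the
#'   adjacent peak via [reflected_pressure()]".
#' @param fixture_cv Multiplicative noise CV on the tied fixture peak.
#' @param ripple Damped post-peak sinusoid for the adjacent sensor:
#'   `amplitude_fraction` (of peak), `frequency_khz`, `decay_ms`.
#' @param noise_sd Additive Gaussian sensor noise, psi. Default 0.25.
#' @param baseline_offset_range Uniform range of the DC offset, psi.
#' @param clip_probability Probability that a shot's sensors saturate.
#' @param saturation_psi Saturation level when clipping occurs (`NA` = at
#'   0.85 of the true peak).
#' @param onset_ms Wave arrival time. Default 1.
#' @param window_ms Record length. Default 8.
#' @param sample_rate Hz. Default 500000.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `shot_config`.
#' @export
shot_config <- function(n_shots = 7L,
                        locations = list(
                          upstream = list(peak = 19.18, duration = 1.99,
                                          decay = 1, rise = 0.019,
                                          cv_peak = 0.065, cv_duration = 0.015),
                          adjacent = list(peak = 20.88, duration = 1.56,
                                          decay = 1.7, rise = 0.030,
                                          cv_peak = 0.10, cv_duration = 0.058),
                          fixture = list(peak = NA_real_, duration = 1.21,
                                         decay = 2.8, rise = 0.027,
                                         cv_peak = 0, cv_duration = 0.20)),
                        fixture_cv = 0.08,
                        ripple = list(amplitude_fraction = 0.15,
                                      frequency_khz = 5, decay_ms = 0.5),
                        noise_sd = 0.25,
                        baseline_offset_range = c(-0.5, 0.5),
                        clip_probability = 0,
                        saturation_psi = NA_real_,
                        onset_ms = 1, window_ms = 8, sample_rate = 5e5,
                        seed = 1L) {
  stopifnot(n_shots >= 1L, noise_sd >= 0,
            clip_probability >= 0, clip_probability <= 1,
            all(c("upstream", "adjacent", "fixture") %in% names(locations)))
  structure(as.list(environment()), class = "shot_config")
}

# one synthetic pulse on the grid: linear rise ramp over `rise` ms, then a
# Friedlander decay whose clock starts at the ramp end
.render_pulse <- function(t, onset, peak, duration, decay, rise) {
  p <- numeric(length(t))
  ramp <- t >= onset & t < onset + rise
  p[ramp] <- peak * (t[ramp] - onset) / rise
  tail <- t >= onset + rise
  u <- (t[tail] - onset - rise) / duration
  p[tail] <- peak * (1 - u) * exp(-decay * u)
  p
}

#' Generate a synthetic shot set with ground truth
#'
#' @param cfg A [shot_config()].
#'
#' @return A list with `traces` (list of [pressure_trace()], one per
#'   shot x sensor) and `truth` (tibble of the generating parameters per
#'   trace: peak, positive duration including the rise ramp, decay
#'   constant, onset, baseline offset, closed-form positive impulse,
#'   clipping status).
#' @export
gen_shot_set <- function(cfg) {
  stopifnot(inherits(cfg, "shot_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$window_ms, by = 1000 / cfg$sample_rate)
  traces <- list()
  rows <- list()
  for (s in seq_len(cfg$n_shots)) {
    shot_id <- sprintf("shot%02d", s)
    adj_peak <- NA_real_
    clip_this <- stats::runif(1) < cfg$clip_probability
    for (loc in c("upstream", "adjacent", "fixture")) {
      L <- cfg$locations[[loc]]
      peak <- if (loc == "fixture" && is.na(L$peak)) {
        reflected_pressure(adj_peak) * max(0.2, stats::rnorm(1, 1, cfg$fixture_cv))
      } else {
        L$peak * max(0.2, stats::rnorm(1, 1, L$cv_peak))
      }
      duration <- L$duration * max(0.2, stats::rnorm(1, 1, L$cv_duration))
      if (loc == "adjacent") adj_peak <- peak
      p <- .render_pulse(t, cfg$onset_ms, peak, duration, L$decay, L$rise)
      if (loc == "adjacent" && cfg$ripple$amplitude_fraction > 0) {
        tail <- t >= cfg$onset_ms + L$rise
        tau <- t[tail] - cfg$onset_ms - L$rise
        p[tail] <- p[tail] + cfg$ripple$amplitude_fraction * peak *
          sin(2 * pi * cfg$ripple$frequency_khz * tau) *
          exp(-tau / cfg$ripple$decay_ms) * (tau / (tau + 0.05))
      }
      offset <- stats::runif(1, cfg$baseline_offset_range[1L],
                             cfg$baseline_offset_range[2L])
      p <- p + offset
      if (cfg$noise_sd > 0) p <- p + stats::rnorm(length(p), 0, cfg$noise_sd)
      sat <- NA_real_
      if (clip_this) {
        sat <- if (is.na(cfg$saturation_psi)) 0.85 * peak else cfg$saturation_psi
        p <- pmin(p, sat)
      }
      traces[[paste(shot_id, loc, sep = "_")]] <-
        pressure_trace(p, time = t, sample_rate = cfg$sample_rate,
                       sensor_location = loc, shot_id = shot_id)
      fp <- friedlander_params(peak, duration, L$decay,
                               cfg$onset_ms + L$rise)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        shot_id = shot_id, sensor_location = loc,
        peak_psi = peak, rise_ms = L$rise,
        positive_duration_ms = L$rise + duration,
        decay_constant = L$decay, onset_ms = cfg$onset_ms,
        impulse_psi_ms = peak * L$rise / 2 + analytic_positive_impulse(fp),
        baseline_offset_psi = offset,
        clipped = clip_this, saturation_psi = sat)
    }
  }
  list(traces = traces, truth = do.call(rbind, rows))
}

#' Trajectory generator configuration
#'
#' A correlated random walk in a square arena with a tunable wall
#' attraction (thigmotaxis). The default step distribution gives a mean
#' path speed of roughly 10 cm/s, in the range of freely exploring rats.
#'
#' @param session_s Session length, s. Default 300 (5 min).
#' @param fps Frames per second. Default 30.
#' @param step_mean Mean step length, cm/frame. Default 0.35.
#' @param step_shape Gamma shape of the step-length distribution. Default 2.
#' @param turn_sd Heading change SD per frame, radians. Default 0.6.
#' @param thigmotaxis_weight Wall attraction strength (>= 0): the fraction
#'   of a mean step drifted toward the nearest wall each frame. 0 gives an
#'   unbiased walk. Default 0.3.
#' @param seed Integer seed.
#'
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(session_s = 300, fps = 30, step_mean = 0.35,
                              step_shape = 2, turn_sd = 0.6,
                              thigmotaxis_weight = 0.3, seed = 1L) {
  stopifnot(session_s > 0, fps > 0, step_mean >= 0, step_shape > 0,
            turn_sd >= 0, thigmotaxis_weight >= 0)
  structure(as.list(environment()), class = "trajectory_config")
}

#' Generate a synthetic open-field trajectory with ground truth
#'
#' Reflected correlated random walk confined to the arena; with zero wall
#' attraction its long-run occupancy is approximately uniform over the
#' arena, so zone dwell fractions approach zone area fractions.
#'
#' @param cfg A [trajectory_config()].
#' @param arena An [arena_spec()].
#' @param subject_id Label stamped on the output.
#'
#' @return A list with `trajectory` (an [oft_trajectory()] carrying nose,
#'   center and tail points) and `truth` (per-frame tibble of the center
#'   point with independent `in_center` / `in_wall` zone labels).
#' @export
gen_trajectory <- function(cfg, arena = arena_spec(), subject_id = "s1") {
  stopifnot(inherits(cfg, "trajectory_config"), inherits(arena, "arena_spec"))
  set.seed(cfg$seed)
  n <- round(cfg$session_s * cfg$fps)
  s <- arena$side_length
  x <- numeric(n); y <- numeric(n)
  x[1L] <- s / 2; y[1L] <- s / 2
  heading <- stats::runif(1, 0, 2 * pi)
  steps <- if (cfg$step_mean > 0)
    stats::rgamma(n, shape = cfg$step_shape,
                  scale = cfg$step_mean / cfg$step_shape) else numeric(n)
  turns <- stats::rnorm(n, 0, cfg$turn_sd)
  for (i in seq_len(n - 1L)) {
    heading <- heading + turns[i]
    dx <- steps[i] * cos(heading)
    dy <- steps[i] * sin(heading)
    if (cfg$thigmotaxis_weight > 0) {
      # drift toward the nearest wall
      dxw <- if (x[i] < s - x[i]) -1 else 1
      dyw <- if (y[i] < s - y[i]) -1 else 1
      if (min(x[i], s - x[i]) <= min(y[i], s - y[i])) {
        dx <- dx + cfg$thigmotaxis_weight * cfg$step_mean * dxw
      } else {
        dy <- dy + cfg$thigmotaxis_weight * cfg$step_mean * dyw
      }
    }
    xn <- x[i] + dx; yn <- y[i] + dy
    # reflect at the walls
    if (xn < 0) xn <- -xn
    if (xn > s) xn <- 2 * s - xn
    if (yn < 0) yn <- -yn
    if (yn > s) yn <- 2 * s - yn
    x[i + 1L] <- min(max(xn, 0), s)
    y[i + 1L] <- min(max(yn, 0), s)
  }
  tsec <- (seq_len(n) - 1L) / cfg$fps
  clamp <- function(v) pmin(pmax(v, 0), s)
  hx <- c(diff(x), 0); hy <- c(diff(y), 0)
  hn <- sqrt(hx^2 + hy^2); hn[hn == 0] <- 1
  frames <- rbind(
    data.frame(t = tsec, point = "center", x = x, y = y),
    data.frame(t = tsec, point = "nose",
               x = clamp(x + 2 * hx / hn), y = clamp(y + 2 * hy / hn)),
    data.frame(t = tsec, point = "tail",
               x = clamp(x - 3 * hx / hn), y = clamp(y - 3 * hy / hn)))
  frames <- frames[order(frames$t), ]
  truth <- tibble::tibble(
    frame = seq_len(n), t = tsec, x = x, y = y,
    in_center = .in_center(x, y, arena),
    in_wall = .in_wall_zone(x, y, arena))
  traj <- oft_trajectory(frames, frame_rate = cfg$fps)
  attr(traj, "subject_id") <- subject_id
  list(trajectory = traj, truth = truth)
}

#' IHC image-set generator configuration
#'
#' Renders marker-positive cells as bright super-Gaussian (flat-topped)
#' disks on a noisy dark background, with Poisson cell counts and
#' configurable blast-group effect multipliers on cell count, cell radius
#' (hence area per cell) and intensity. Defaults emulate a microglial
#' (Iba1-like) activation pattern: more, smaller, brighter cells in the
#' blast group.
#'
#' @param n_images Images per group. Default 12.
#' @param images_per_subject Representative images averaged per subject.
#'   Default 6.
#' @param image_size Image side, pixels. Default 256.
#' @param scale Micrometers per pixel. Default 0.65.
#' @param n_cells_mean Mean cell count per sham image. Default 35.
#' @param radius_um_mean,radius_um_sd Cell radius distribution, um.
#'   Defaults 5 and 0.7 (mean footprint ~80 um^2).
#' @param fg_mean,fg_sd Per-cell peak intensity distribution. Defaults 180,
#'   15 (arbitrary camera units).
#' @param bg_level,noise_sd Background level and additive noise SD.
#'   Defaults 12 and 8.
#' @param count_effect,radius_effect,intensity_effect Blast-group
#'   multipliers. Defaults 1.5, 0.87, 1.3 (count up ~50%, area per cell
#'   down ~25%, intensity up ~30%).
#' @param channel Marker label. Default `"Iba1"`.
#' @param seed Integer seed.
#'
#' @return An object of class `ihc_config`.
#' @export
ihc_config <- function(n_images = 12L, images_per_subject = 6L,
                       image_size = 256L, scale = 0.65,
                       n_cells_mean = 35, radius_um_mean = 5,
                       radius_um_sd = 0.7, fg_mean = 180, fg_sd = 15,
                       bg_level = 12, noise_sd = 8,
                       count_effect = 1.5, radius_effect = 0.87,
                       intensity_effect = 1.3, channel = "Iba1",
                       seed = 1L) {
  stopifnot(n_images >= 1L, image_size >= 32L, scale > 0, n_cells_mean >= 0,
            radius_um_mean > 0, fg_mean > 0, bg_level >= 0, noise_sd >= 0,
            is.finite(count_effect), is.finite(radius_effect),
            is.finite(intensity_effect))
  structure(as.list(environment()), class = "ihc_config")
}

# render one image; returns pixels, ground-truth mask and cell count
.render_ihc <- function(size, scale, n_cells, radius_um_mean, radius_um_sd,
                        fg_mean, fg_sd, bg_level, noise_sd) {
  px <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  xs <- seq_len(size); ys <- seq_len(size)
  placed <- matrix(numeric(0), ncol = 3L)  # cx, cy, r (px)
  for (k in seq_len(n_cells)) {
    r <- max(2, stats::rnorm(1, radius_um_mean, radius_um_sd) / scale)
    ok <- FALSE
    for (try in 1:200) {
      cx <- stats::runif(1, r + 1, size - r - 1)
      cy <- stats::runif(1, r + 1, size - r - 1)
      if (nrow(placed) == 0L ||
          all((placed[, 1L] - cx)^2 + (placed[, 2L] - cy)^2 >
              (placed[, 3L] + r + 2)^2)) { ok <- TRUE; break }
    }
    if (!ok) next  # field too crowded; skip this cell
    placed <- rbind(placed, c(cx, cy, r))
    peak <- max(1, stats::rnorm(1, fg_mean, fg_sd))
    # restrict rendering to a local window for speed
    wx <- xs[abs(xs - cx) <= 2.5 * r]
    wy <- ys[abs(ys - cy) <= 2.5 * r]
    d2 <- outer((wx - cx)^2, (wy - cy)^2, "+")
    px[wx, wy] <- px[wx, wy] + peak * exp(-log(2) * (d2 / r^2)^3)
    mask[wx, wy] <- mask[wx, wy] | d2 <= r^2
  }
  px <- px + bg_level
  if (noise_sd > 0) px <- px + matrix(stats::rnorm(size^2, 0, noise_sd), size)
  list(pixels = pmax(px, 0), mask = mask, n_cells = nrow(placed))
}

#' Generate a two-group synthetic IHC image set with ground truth
#'
#' @param cfg An [ihc_config()].
#'
#' @return A list with `images` (list of [fluorescence_image()]s for both
#'   groups), `masks` (ground-truth cell masks, same order) and `truth`
#'   (tibble: image id, group, subject, true cell count, true positive-area
#'   fraction).
#' @export
gen_ihc_image_set <- function(cfg) {
  stopifnot(inherits(cfg, "ihc_config"))
  set.seed(cfg$seed)
  images <- list(); masks <- list(); rows <- list()
  for (grp in c("sham", "blast")) {
    eff_n <- if (grp == "blast") cfg$count_effect else 1
    eff_r <- if (grp == "blast") cfg$radius_effect else 1
    eff_i <- if (grp == "blast") cfg$intensity_effect else 1
    for (i in seq_len(cfg$n_images)) {
      subject <- sprintf("%s%02d", substr(grp, 1, 2),
                         ceiling(i / cfg$images_per_subject))
      n_cells <- stats::rpois(1, cfg$n_cells_mean * eff_n)
      r <- .render_ihc(cfg$image_size, cfg$scale, n_cells,
                       cfg$radius_um_mean * eff_r, cfg$radius_um_sd * eff_r,
                       cfg$fg_mean * eff_i, cfg$fg_sd, cfg$bg_level,
                       cfg$noise_sd)
      id <- sprintf("%s_%s_img%02d", cfg$channel, grp, i)
      images[[id]] <- fluorescence_image(r$pixels, scale = cfg$scale,
                                         channel = cfg$channel,
                                         subject_id = subject, group = grp)
      masks[[id]] <- r$mask
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = id, group = grp, subject_id = subject,
        true_cell_count = r$n_cells, true_area_fraction = mean(r$mask))
    }
  }
  list(images = images, masks = masks, truth = do.call(rbind, rows))
}
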