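#' Read a pressure-trace file
#'
#' Two-column delimited text with a header declaring the units, e.g.
#' `time_ms,pressure_psi` or `time_s,pressure_kpa`. Units are normalized to
#' ms and psi on read (1 psi = 6.894757 kPa). Malformed input — a header
#' without units, ragged rows, non-numeric cells, or a non-uniform time
#' grid — raises a descriptive error naming the offending line.
#'
#' @param path File path.
#' @param sensor_location,shot_id Labels for the resulting trace.
#' @param sep Field separator. Default `","`.
#'
#' @return A [pressure_trace()].
#' @export
read_trace_file <- function(path, sensor_location = "upstream",
                            shot_id = "shot", sep = ",") {
  if (!file.exists(path)) stop("no such trace file: ", path)
  nf <- utils::count.fields(path, sep = sep, comment.char = "#")
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(path, " line ", bad, ": expected 2 fields, found ", nf[bad])
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", comment.char = "#")
  units <- lapply(names(raw), function(h) {
    m <- regmatches(h, regexec("^(time|pressure)_([a-zA-Z]+)$", h))[[1L]]
    if (length(m) == 0L)
      stop(path, ": header column '", h,
           "' must declare units, e.g. time_ms or pressure_psi")
    m[2:3]
  })
  kinds <- vapply(units, `[`, character(1), 1L)
  if (!setequal(kinds, c("time", "pressure")))
    stop(path, ": need one time_* and one pressure_* column")
  vals <- lapply(seq_along(raw), function(j) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(path, " line ", bad + 1L, ": non-numeric value '",
           raw[bad, j], "' in column ", names(raw)[j])
    }
    v
  })
  ti <- which(kinds == "time")
  time <- switch(tolower(units[[ti]][2L]),
                 ms = vals[[ti]], s = vals[[ti]] * 1000,
                 stop(path, ": unsupported time unit '", units[[ti]][2L], "'"))
  pi_ <- which(kinds == "pressure")
  pressure <- switch(tolower(units[[pi_]][2L]),
                     psi = vals[[pi_]], kpa = vals[[pi_]] / 6.894757,
                     stop(path, ": unsupported pressure unit '",
                          units[[pi_]][2L], "'"))
  pressure_trace(pressure, time = time, sensor_location = sensor_location,
                 shot_id = shot_id)
}

#' Write a pressure trace as delimited text
#'
#' Written as `time_ms,pressure_psi` at full double precision, so a
#' write/read round trip reproduces the trace exactly.
#'
#' @param trace A [pressure_trace()].
#' @param path Output path.
#' @export
write_trace_file <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  lines <- c("time_ms,pressure_psi",
             sprintf("%.17g,%.17g", trace$time, trace$pressure))
  writeLines(lines, path)
  invisible(path)
}

#' Read a shot manifest and its traces
#'
#' The manifest is a CSV with columns `shot_id`, `sensor_location`, `path`
#' (relative paths resolved against the manifest's directory).
#'
#' @param manifest_path Manifest CSV path.
#'
#' @return A list of [pressure_trace()]s named `<shot_id>_<sensor_location>`.
#' @export
read_shot_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, colClasses = "character")
  need <- c("shot_id", "sensor_location", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  traces <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_trace_file(p, sensor_location = man$sensor_location[i],
                    shot_id = man$shot_id[i])
  })
  names(traces) <- paste(man$shot_id, man$sensor_location, sep = "_")
  traces
}

#' Read a tracking export CSV as a trajectory
#'
#' Expected columns: `time_s`, `point`, `x_cm`, `y_cm`, and optionally
#' `subject_id` and `group` (returned as attributes).
#'
#' @param path CSV path.
#' @param frame_rate Frames per second. Default 30.
#'
#' @return An [oft_trajectory()].
#' @export
read_tracks_file <- function(path, frame_rate = 30) {
  if (!file.exists(path)) stop("no such tracks file: ", path)
  d <- utils::read.csv(path)
  need <- c("time_s", "point", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop(path, ": tracks file must have columns ", paste(need, collapse = ", "))
  traj <- oft_trajectory(
    data.frame(t = d$time_s, point = d$point, x = d$x_cm, y = d$y_cm),
    frame_rate = frame_rate)
  if ("subject_id" %in% names(d))
    attr(traj, "subject_id") <- d$subject_id[1L]
  if ("group" %in% names(d)) attr(traj, "group") <- d$group[1L]
  traj
}

#' Write a trajectory as a tracking export CSV
#'
#' @param traj An [oft_trajectory()].
#' @param path Output path.
#' @export
write_tracks_file <- function(traj, path) {
  stopifnot(inherits(traj, "oft_trajectory"))
  d <- data.frame(time_s = traj$t, point = traj$point,
                  x_cm = traj$x, y_cm = traj$y)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
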