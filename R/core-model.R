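# Core domain types and session I/O.
#
# Time is always seconds (float); camera coordinates are pixels and are
# converted to cm exactly once, at load (position_series stores both the pixel
# values and the conversion factor; accessors return cm). Sessions are stored
# on disk as a JSON manifest plus delimited-text tables, so fixtures are
# diffable and language-agnostic.

#' Tracked position series
#'
#' @param timestamps seconds, strictly increasing; dropouts (gaps) are allowed
#' @param x,y position in pixels
#' @param px_per_cm pixels per cm (> 0)
#' @param nominal_rate nominal camera rate, Hz
#' @return a `position_series` object
#' @export
position_series <- function(timestamps, x, y, px_per_cm, nominal_rate = 30) {
  stopifnot(length(timestamps) == length(x), length(x) == length(y))
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(px_per_cm) || px_per_cm <= 0) stop("px_per_cm must be > 0")
  structure(list(timestamps = as.numeric(timestamps),
                 x = as.numeric(x), y = as.numeric(y),
                 px_per_cm = px_per_cm, nominal_rate = nominal_rate),
            class = "position_series")
}

#' Position in cm
#' @param pos a `position_series`
#' @return data.frame t, x, y with coordinates in cm
#' @export
pos_cm <- function(pos) {
  data.frame(t = pos$timestamps, x = pos$x / pos$px_per_cm,
             y = pos$y / pos$px_per_cm)
}

#' Spike train of one unit
#'
#' @param unit_id character id
#' @param region `"HPC"` or `"LS"`
#' @param spike_times seconds; sorted ascending (unsorted input is sorted with
#'   a warning)
#' @param session_id character
#' @export
spike_train <- function(unit_id, region, spike_times, session_id = "") {
  region <- match.arg(region, c("HPC", "LS"))
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    warning("spike times for unit ", unit_id, " were unsorted; sorting")
    spike_times <- sort(spike_times)
  }
  structure(list(unit_id = as.character(unit_id), region = region,
                 spike_times = spike_times, session_id = as.character(session_id)),
            class = "spike_train")
}

#' Analysis configuration
#'
#' Houses every threshold of the pipeline. Defaults are the study constants:
#' 12 cm/s speed filter, 1 cm information bins, 2 cm field bins, 10 cm map
#' smoothing, 1 s speed smoothing, 0.8 bits/spike cutoff, 15 cm minimum field
#' length, 0.05 Hz rate floor, 20 cm pair-match radius, 10 ms correlogram bins
#' over a +/-100 ms lag range.
#'
#' @param speed_threshold cm/s
#' @param info_bin cm (information maps)
#' @param field_bin cm (field maps)
#' @param map_smooth_sd cm
#' @param speed_smooth_sd s
#' @param bits_cutoff bits/spike
#' @param min_field_len cm
#' @param rate_floor Hz
#' @param match_radius cm
#' @param ccg_bin ms
#' @param ccg_maxlag ms
#' @param n_shuffles shuffles for the correlogram control
#' @param rng_seed base seed
#' @export
analysis_config <- function(speed_threshold = 12, info_bin = 1, field_bin = 2,
                            map_smooth_sd = 10, speed_smooth_sd = 1,
                            bits_cutoff = 0.8, min_field_len = 15,
                            rate_floor = 0.05, match_radius = 20,
                            ccg_bin = 10, ccg_maxlag = 100,
                            n_shuffles = 100, rng_seed = 1) {
  cfg <- list(speed_threshold = speed_threshold, info_bin = info_bin,
              field_bin = field_bin, map_smooth_sd = map_smooth_sd,
              speed_smooth_sd = speed_smooth_sd, bits_cutoff = bits_cutoff,
              min_field_len = min_field_len, rate_floor = rate_floor,
              match_radius = match_radius, ccg_bin = ccg_bin,
              ccg_maxlag = ccg_maxlag, n_shuffles = n_shuffles,
              rng_seed = rng_seed)
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) <= 0))
    stop("all analysis_config thresholds must be positive numbers")
  structure(cfg, class = "analysis_config")
}

#' Recording session
#'
#' Bundles positions, spike trains, maze geometry, and trial events. Session
#' bounds are the first and last position timestamps; spikes outside the
#' bounds are dropped with a message giving the count.
#'
#' @param positions a `position_series`
#' @param trains list of `spike_train`
#' @param maze a `maze_geometry`
#' @param events data.frame with columns `time`, `event`
#'   (`trial_start` / `choice_arrival` / `reward`), `arm`, `correct`
#' @param session_id character
#' @export
session <- function(positions, trains, maze, events = NULL, session_id = "s1") {
  stopifnot(inherits(positions, "position_series"), inherits(maze, "maze_geometry"))
  t0 <- positions$timestamps[1]
  t1 <- positions$timestamps[length(positions$timestamps)]
  trains <- lapply(trains, function(tr) {
    stopifnot(inherits(tr, "spike_train"))
    keep <- tr$spike_times >= t0 & tr$spike_times <= t1
    if (any(!keep)) {
      message("unit ", tr$unit_id, ": dropped ", sum(!keep),
              " spikes outside session bounds")
      tr$spike_times <- tr$spike_times[keep]
    }
    tr$session_id <- session_id
    tr
  })
  if (!is.null(events)) {
    stopifnot(all(c("time", "event") %in% names(events)))
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(positions = positions, trains = trains, maze = maze,
                 events = events, session_id = session_id,
                 t0 = t0, t1 = t1, duration = t1 - t0),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat("Session", x$session_id, ":", length(x$trains), "units,",
      length(x$positions$timestamps), "position samples,",
      round(x$duration, 1), "s\n")
  invisible(x)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a session to disk
#'
#' Writes one CSV position table (`t,x,y`), one single-column CSV per unit
#' (`t`), the trial-event table, and a JSON manifest tying them together with
#' the maze parameters. Numbers are printed with 17 significant digits so a
#' write/read/write cycle is byte-identical.
#'
#' @param sess a `session`
#' @param dir output directory (created if needed)
#' @return path of the manifest
#' @export
write_session <- function(sess, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  p <- sess$positions
  pos_file <- file.path(dir, "positions.csv")
  writeLines(c("t,x,y", paste(.fmt(p$timestamps), .fmt(p$x), .fmt(p$y), sep = ",")),
             pos_file)
  units <- lapply(sess$trains, function(tr) {
    f <- paste0("spikes_", tr$unit_id, ".csv")
    writeLines(c("t", .fmt(tr$spike_times)), file.path(dir, f))
    list(unit_id = tr$unit_id, region = tr$region, file = f)
  })
  ev <- NULL
  if (!is.null(sess$events)) {
    ev_file <- file.path(dir, "events.csv")
    e <- sess$events
    writeLines(c("time,event,arm,correct",
                 paste(.fmt(e$time), e$event, e$arm,
                       as.integer(e$correct), sep = ",")), ev_file)
    ev <- "events.csv"
  }
  manifest <- list(session_id = sess$session_id,
                   positions = "positions.csv",
                   px_per_cm = p$px_per_cm, nominal_rate = p$nominal_rate,
                   maze = list(arm_length = sess$maze$arm_length,
                               stem_length = sess$maze$stem_length),
                   units = units, events = ev)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mpath
}

.read_num_csv <- function(path, ncol) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                 warning = function(w) stop("parse error in ", path, ": ",
                                            conditionMessage(w)),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (anyNA(df)) stop("parse error in ", path, ": non-numeric field at line ",
                      which(rowSums(is.na(df)) > 0)[1] + 1L)
  df
}

#' Read a session from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by [write_session()]
#' @return a validated `session`
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("missing file: ", manifest_path)
  m <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  pdf <- .read_num_csv(file.path(dir, m$positions))
  pos <- position_series(pdf$t, pdf$x, pdf$y, px_per_cm = m$px_per_cm,
                         nominal_rate = m$nominal_rate)
  trains <- lapply(m$units, function(u) {
    sdf <- .read_num_csv(file.path(dir, u$file))
    spike_train(u$unit_id, u$region, sdf$t, session_id = m$session_id)
  })
  events <- NULL
  if (!is.null(m$events)) {
    e <- utils::read.csv(file.path(dir, m$events),
                         colClasses = c("numeric", "character", "character",
                                        "integer"))
    events <- data.frame(time = e$time, event = e$event, arm = e$arm,
                         correct = as.logical(e$correct),
                         stringsAsFactors = FALSE)
  }
  maze <- build_maze(m$maze$arm_length, m$maze$stem_length)
  session(pos, trains, maze, events = events, session_id = m$session_id)
}
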