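# Speed/acceleration, speed filtering, occupancy and firing-rate maps.
#
# Occupancy is accumulated over the linearized track in half-open bins.
# Each position sample contributes a dwell time equal to half the gap to its
# neighbours, capped at 1 s so tracking dropouts do not inflate occupancy.
# Rate maps are ratio-then-smooth: per-bin spikes/dwell is computed first and
# then smoothed with a mask-normalized Gaussian kernel over geodesic
# (along-maze) distance, so smoothing never crosses between physically
# unconnected arms and unvisited bins never leak zeros into the map.

#' Speed from tracked positions
#'
#' Per-sample speed is the hypotenuse distance between the samples
#' immediately before and after the time point, divided by their time gap
#' (one-sided differences at the ends), converted from pixels to cm/s, then
#' Gaussian-smoothed over time.
#'
#' @param pos a `position_series`
#' @param smooth_sd temporal smoothing SD, s (default 1)
#' @return a `kinematics` object: timestamps, speed (cm/s), and the raw
#'   unsmoothed speed
#' @export
compute_speed <- function(pos, smooth_sd = 1) {
  t <- pos$timestamps
  n <- length(t)
  if (n < 3) stop("need at least 3 position samples to compute speed")
  ip <- c(1, 1:(n - 1)); inx <- c(2:n, n)  # one-sided at the ends
  d <- sqrt((pos$x[inx] - pos$x[ip])^2 + (pos$y[inx] - pos$y[ip])^2)
  raw <- d / (t[inx] - t[ip]) / pos$px_per_cm
  sm <- gauss_smooth_time(t, raw, smooth_sd, rate = pos$nominal_rate)
  structure(list(timestamps = t, speed = pmax(sm, 0), speed_raw = raw,
                 acceleration = NULL), class = "kinematics")
}

#' Acceleration from smoothed speed
#'
#' Central difference of the smoothed speed (one-sided at the ends).
#'
#' @param kin a `kinematics` object from [compute_speed()]
#' @return the same object with `acceleration` (cm/s^2) filled in
#' @export
compute_acceleration <- function(kin) {
  t <- kin$timestamps; v <- kin$speed
  n <- length(t)
  ip <- c(1, 1:(n - 1)); inx <- c(2:n, n)
  kin$acceleration <- (v[inx] - v[ip]) / (t[inx] - t[ip])
  kin
}

# dwell time per sample: half-gap to neighbours, capped to guard dropouts
.dwell_times <- function(t, cap = 1) {
  n <- length(t)
  if (n == 1) return(cap)
  gaps <- diff(t)
  pmin((c(gaps, 0) + c(0, gaps)) / 2, cap)
}

#' Filter positions and spikes by running speed
#'
#' Retains position samples whose smoothed speed is at or above `threshold`
#' and spikes whose linearly interpolated speed at the spike time is at or
#' above `threshold`. Dwell times are computed from the full series before
#' filtering. Position samples are also linearized; off-track samples are
#' dropped.
#'
#' @param pos a `position_series`
#' @param kin matching `kinematics`
#' @param trains list of `spike_train` (or a single train)
#' @param threshold cm/s
#' @param maze a `maze_geometry`
#' @return list with `positions` (data.frame t, x, y (cm), lin, arm, speed,
#'   accel, dwell), `trains` (filtered spike trains), `total_time` (s), and
#'   `n_dropped_off_track`
#' @export
speed_filter <- function(pos, kin, trains, threshold, maze) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (inherits(trains, "spike_train")) trains <- list(trains)
  pc <- pos_cm(pos)
  dwell <- .dwell_times(pc$t)
  lp <- linearize(pc$x, pc$y, maze)
  fast <- kin$speed >= threshold & !lp$off_track
  fpos <- data.frame(t = pc$t[fast], x = pc$x[fast], y = pc$y[fast],
                     lin = lp$lin[fast], arm = lp$arm[fast],
                     speed = kin$speed[fast],
                     accel = if (!is.null(kin$acceleration)) kin$acceleration[fast] else NA_real_,
                     dwell = dwell[fast], stringsAsFactors = FALSE)
  ftrains <- lapply(trains, function(tr) {
    sv <- stats::approx(kin$timestamps, kin$speed, xout = tr$spike_times,
                        rule = 2)$y
    tr$spike_times <- tr$spike_times[sv >= threshold]
    tr
  })
  list(positions = fpos, trains = ftrains,
       total_time = sum(fpos$dwell),
       n_dropped_off_track = sum(lp$off_track))
}

#' Occupancy map over the linearized track
#'
#' Per-bin occupancy probability P_i = dwell_i / total dwell over visited
#' bins; unvisited bins are masked.
#'
#' @param fpos filtered positions (the `positions` element of
#'   [speed_filter()])
#' @param grid a `track_grid`
#' @return an `occupancy_map`: `P`, `dwell` (s), `visited`, `total_time`,
#'   `grid`
#' @export
occupancy_map <- function(fpos, grid) {
  if (nrow(fpos) == 0) stop("no position samples above the speed threshold")
  b <- .grid_bin(grid, fpos$lin)
  ok <- !is.na(b)
  n <- nrow(grid$bins)
  dwell <- as.numeric(tapply(fpos$dwell[ok], factor(b[ok], levels = seq_len(n)), sum))
  dwell[is.na(dwell)] <- 0
  total <- sum(dwell)
  if (total <= 0) stop("zero total occupancy time")
  structure(list(P = dwell / total, dwell = dwell, visited = dwell > 0,
                 total_time = total, grid = grid, bin_size = grid$bin_size),
            class = "occupancy_map")
}

# mask-normalized Gaussian smoothing over geodesic bin distance
.smooth_masked <- function(values, grid, visited, sd_cm) {
  if (sd_cm <= 0) return(values)
  K <- exp(-grid$D^2 / (2 * sd_cm^2))
  K[, !visited] <- 0
  den <- K %*% visited
  num <- K %*% (values * visited)
  out <- as.numeric(num / pmax(den, .Machine$double.eps))
  out[!visited] <- 0
  out
}

#' Firing-rate map
#'
#' Raw per-bin rate R_i = spike count / dwell time on visited bins, smoothed
#' with a mask-normalized Gaussian kernel over along-track distance. The
#' overall mean rate is total filtered spikes / total filtered time.
#'
#' @param ftrain a speed-filtered `spike_train`
#' @param fpos filtered positions (for spike-to-position interpolation)
#' @param occ an `occupancy_map` on the target grid
#' @param smooth_sd kernel SD, cm
#' @return a `rate_map`: `rate` (smoothed), `rate_raw`, `mean_rate`,
#'   `visited`, `grid`, `unit_id`
#' @export
rate_map <- function(ftrain, fpos, occ, smooth_sd = 10) {
  if (occ$total_time <= 0) stop("occupancy map has zero total time")
  st <- ftrain$spike_times
  # spike position = linearized coordinate of the nearest-in-time fast sample
  lin <- if (length(st)) {
    idx <- findInterval(st, fpos$t, all.inside = TRUE)
    use_next <- abs(fpos$t[pmin(idx + 1L, nrow(fpos))] - st) < abs(fpos$t[idx] - st)
    fpos$lin[ifelse(use_next, pmin(idx + 1L, nrow(fpos)), idx)]
  } else numeric(0)
  b <- .grid_bin(occ$grid, lin)
  n <- nrow(occ$grid$bins)
  cnt <- tabulate(b[!is.na(b)], nbins = n)
  raw <- ifelse(occ$visited, cnt / pmax(occ$dwell, .Machine$double.eps), 0)
  sm <- .smooth_masked(raw, occ$grid, occ$visited, smooth_sd)
  structure(list(rate = sm, rate_raw = raw, counts = cnt,
                 mean_rate = length(st) / occ$total_time,
                 visited = occ$visited, grid = occ$grid,
                 bin_size = occ$bin_size, smooth_sd = smooth_sd,
                 unit_id = ftrain$unit_id), class = "rate_map")
}

#' Check full track coverage at running speed
#'
#' TRUE iff every track bin is visited by at least one speed-filtered sample.
#'
#' @param fpos filtered positions
#' @param grid a `track_grid`
#' @export
check_track_coverage <- function(fpos, grid) {
  b <- .grid_bin(grid, fpos$lin)
  length(unique(b[!is.na(b)])) == nrow(grid$bins)
}

#' Per-bin mean kinematics maps
#'
#' Dwell-weighted mean speed and acceleration per track bin, used by the
#' speed/acceleration regression control.
#'
#' @param fpos filtered positions (with `speed`, `accel`, `dwell`)
#' @param grid a `track_grid`
#' @return data.frame bin, speed, accel (NA on unvisited bins)
#' @export
kinematics_maps <- function(fpos, grid) {
  b <- .grid_bin(grid, fpos$lin)
  ok <- !is.na(b)
  n <- nrow(grid$bins)
  f <- factor(b[ok], levels = seq_len(n))
  wsum <- as.numeric(tapply(fpos$dwell[ok], f, sum))
  sp <- as.numeric(tapply(fpos$dwell[ok] * fpos$speed[ok], f, sum)) / wsum
  ac <- as.numeric(tapply(fpos$dwell[ok] * fpos$accel[ok], f, sum)) / wsum
  data.frame(bin = seq_len(n), speed = sp, accel = ac)
}
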