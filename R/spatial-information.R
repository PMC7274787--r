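# Spatial information: bits/spike, bits/second, mutual information,
# place-information classification, and the Poisson surrogate control.

#' Skaggs spatial information per spike
#'
#' \deqn{bits/spike = \sum_i P_i (R_i/\bar R) \log_2(R_i/\bar R)}
#' over visited bins, with 0 log 0 := 0.
#'
#' @param rm a `rate_map`
#' @param occ the matching `occupancy_map` (same grid)
#' @return bits per spike (>= 0 up to floating error)
#' @export
bits_per_spike <- function(rm, occ) {
  if (!identical(dim(rm$grid$D), dim(occ$grid$D)) ||
      rm$bin_size != occ$bin_size)
    stop("rate map and occupancy map are on different grids")
  v <- occ$visited
  P <- occ$P[v]; R <- rm$rate[v]
  Rbar <- sum(P * R)
  if (Rbar <= 0) stop("overall mean rate is zero; information undefined")
  x <- R / Rbar
  term <- ifelse(x > 0, P * x * log2(x), 0)
  sum(term)
}

#' Skaggs spatial information per second
#'
#' \deqn{bits/s = \sum_i P_i R_i \log_2(R_i/\bar R)}; algebraically equal to
#' mean rate times bits/spike.
#'
#' @inheritParams bits_per_spike
#' @export
bits_per_second <- function(rm, occ) {
  v <- occ$visited
  P <- occ$P[v]; R <- rm$rate[v]
  Rbar <- sum(P * R)
  if (Rbar <= 0) stop("overall mean rate is zero; information undefined")
  x <- R / Rbar
  sum(ifelse(x > 0, P * R * log2(x), 0))
}

#' Plug-in mutual information between spike counts and position
#'
#' Discrete MI between the spike count in one-sample windows (counts clipped
#' at `k_max`) and the occupied spatial bin, using the plug-in estimator on
#' the speed-filtered samples. This is a standard discretized estimator,
#' reported as a supplementary measure alongside bits/spike.
#'
#' @param ftrain speed-filtered `spike_train`
#' @param fpos filtered positions
#' @param grid a `track_grid`
#' @param k_max count clip (default 3)
#' @return mutual information, bits
#' @export
mutual_information <- function(ftrain, fpos, grid, k_max = 3) {
  if (nrow(fpos) < 2) stop("need at least 2 filtered samples")
  b <- .grid_bin(grid, fpos$lin)
  ok <- !is.na(b)
  # one-sample windows: [t_i, t_{i+1}) capped at 0.2 s
  t <- fpos$t
  w <- pmin(c(diff(t), stats::median(diff(t))), 0.2)
  sp <- ftrain$spike_times
  cnt <- findInterval(t + w - 1e-12, sp) - findInterval(t - 1e-12, sp)
  k <- pmin(cnt, k_max)[ok]
  bb <- b[ok]
  tab <- table(k, bb)
  pj <- tab / sum(tab)
  pk <- rowSums(pj); pb <- colSums(pj)
  e <- outer(pk, pb)
  sum(ifelse(pj > 0, pj * log2(pj / e), 0))
}

#' Classify units by spatial information
#'
#' Runs the full information pipeline per unit on 1 cm maps: speed filtering,
#' occupancy, smoothed rate map, bits/spike, bits/second, and MI. Units with
#' speed-filtered mean rate below the rate floor are excluded as `low_rate`;
#' if the animal did not cover the whole track at running speed, all units
#' are excluded as `no_coverage`. A unit passes the cutoff iff its bits/spike
#' meets or exceeds `bits_cutoff` and it is not excluded.
#'
#' @param sess a `session`
#' @param config an `analysis_config`
#' @param trains optional list of trains to analyze instead of the session's
#'   (used by the surrogate control)
#' @return data.frame: unit_id, region, mean_rate, bits_per_spike,
#'   bits_per_second, mutual_info, passes_cutoff, excluded_reason
#' @export
classify_units <- function(sess, config = analysis_config(), trains = NULL) {
  trains <- trains %||% sess$trains
  kin <- compute_acceleration(compute_speed(sess$positions, config$speed_smooth_sd))
  filt <- speed_filter(sess$positions, kin, trains, config$speed_threshold,
                       sess$maze)
  grid <- track_grid(sess$maze, config$info_bin)
  covered <- check_track_coverage(filt$positions, track_grid(sess$maze, config$field_bin))
  occ <- occupancy_map(filt$positions, grid)
  rows <- lapply(filt$trains, function(tr) {
    count_rate <- length(tr$spike_times) / occ$total_time
    out <- data.frame(unit_id = tr$unit_id, region = tr$region,
                      mean_rate = count_rate, bits_per_spike = NA_real_,
                      bits_per_second = NA_real_, mutual_info = NA_real_,
                      passes_cutoff = FALSE, excluded_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!covered) { out$excluded_reason <- "no_coverage"; return(out) }
    if (count_rate < config$rate_floor) { out$excluded_reason <- "low_rate"; return(out) }
    rm <- rate_map(tr, filt$positions, occ, config$map_smooth_sd)
    out$bits_per_spike <- bits_per_spike(rm, occ)
    # the reported mean rate is the occupancy-weighted map rate (the R-bar of
    # the information formulas), so bits/s = mean_rate * bits/spike exactly
    out$mean_rate <- sum(occ$P[occ$visited] * rm$rate[occ$visited])
    out$bits_per_second <- bits_per_second(rm, occ)
    out$mutual_info <- mutual_information(tr, filt$positions, grid)
    out$passes_cutoff <- out$bits_per_spike >= config$bits_cutoff
    out
  })
  do.call(rbind, rows)
}

#' Poisson surrogate population control
#'
#' Generates `n_units` homogeneous Poisson trains over the session timeline
#' (rates cycled from `rates`) and runs them through the identical
#' occupancy/rate/information pipeline on the session's trajectory. Used to
#' check that observed spatial information exceeds what random firing yields.
#'
#' @param sess a `session`
#' @param n_units number of surrogate units
#' @param rates vector of mean rates, Hz (cycled)
#' @param seed RNG seed
#' @param config an `analysis_config`
#' @return the [classify_units()] table for the surrogate units
#' @export
surrogate_population <- function(sess, n_units, rates, seed = 1,
                                 config = analysis_config()) {
  if (!length(rates)) stop("rates must be nonempty")
  rates <- rep_len(rates, n_units)
  trains <- lapply(seq_len(n_units), function(i) {
    tr <- generate_poisson_unit(rates[i], sess$duration,
                                seed = child_seed(seed, i),
                                unit_id = sprintf("surr%03d", i), region = "LS")
    tr$spike_times <- tr$spike_times + sess$t0
    tr
  })
  classify_units(sess, config, trains = trains)
}
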