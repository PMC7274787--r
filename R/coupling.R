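# HPC-LS pair matching and shuffle-corrected spike cross-correlograms.
#
# Correlogram convention: positive lag means LS activity follows HPC
# (HPC leads). Values are binned-count cross-products normalized per bin by
# default; "rate" and "pearson" normalizations are available. The shuffle
# control circularly time-shifts the LS train (preserving its ISI structure
# and rate), and the scalar mean of the control correlogram over lags and
# shuffles is subtracted from every lag bin.

.bin_counts <- function(times, t0, t1, bin_s) {
  edges <- seq(t0, t1 + bin_s, by = bin_s)
  tabulate(findInterval(times[times >= t0 & times < edges[length(edges)]],
                        edges, rightmost.closed = FALSE),
           nbins = length(edges) - 1)
}

#' Raw spike-train cross-correlogram
#'
#' Both trains are binned at `ccg_bin` ms over their common session span and
#' the lagged cross-product is taken at lags -`ccg_maxlag` ... +`ccg_maxlag`.
#'
#' @param hpc,ls `spike_train`s (HPC first; positive lag = HPC leads)
#' @param config an `analysis_config`
#' @param t_range optional c(t0, t1) restricting the analysis window
#' @param normalization `"counts"` (cross-product per bin, default),
#'   `"rate"` (per second^2), or `"pearson"`
#' @return list: `lags_ms`, `raw`, `nbins`, `normalization`
#' @export
cross_correlogram <- function(hpc, ls, config = analysis_config(),
                              t_range = NULL,
                              normalization = c("counts", "rate", "pearson")) {
  normalization <- match.arg(normalization)
  if (!length(hpc$spike_times)) stop("empty spike train: ", hpc$unit_id)
  if (!length(ls$spike_times)) stop("empty spike train: ", ls$unit_id)
  if (is.null(t_range))
    t_range <- range(c(hpc$spike_times, ls$spike_times))
  bin_s <- config$ccg_bin / 1000
  x <- .bin_counts(hpc$spike_times, t_range[1], t_range[2], bin_s)
  y <- .bin_counts(ls$spike_times, t_range[1], t_range[2], bin_s)
  nlag <- round(config$ccg_maxlag / config$ccg_bin)
  lags <- (-nlag):nlag
  n <- length(x)
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)])
  }, numeric(1))
  raw <- switch(normalization,
                counts = vals / n,
                rate = vals / n / bin_s^2,
                pearson = {
                  sx <- stats::sd(x); sy <- stats::sd(y)
                  (vals / n - mean(x) * mean(y)) / ifelse(sx * sy > 0, sx * sy, 1)
                })
  list(lags_ms = lags * config$ccg_bin, raw = raw, nbins = n,
       normalization = normalization, t_range = t_range,
       hpc_unit = hpc$unit_id, ls_unit = ls$unit_id)
}

#' Shuffle-corrected cross-correlogram
#'
#' Computes `n_shuffles` control correlograms against circularly time-shifted
#' copies of the LS train (uniform offset at least 1 s), takes the scalar
#' mean of the controls over lags and shuffles, and subtracts it from every
#' lag of the raw correlogram.
#'
#' @param raw_ccg result of [cross_correlogram()]
#' @param hpc,ls the original `spike_train`s
#' @param config an `analysis_config` (uses `n_shuffles`)
#' @param seed RNG seed
#' @return a `cross_correlogram` object: lags_ms, raw, corrected,
#'   shuffle_mean, shuffle_sd, mean_corrected, peak_lag_ms, n_shuffles, seed
#' @export
shuffle_correct <- function(raw_ccg, hpc, ls, config = analysis_config(),
                            seed = 1) {
  n_shuffles <- max(1L, as.integer(config$n_shuffles))
  set.seed(seed)
  t0 <- raw_ccg$t_range[1]; t1 <- raw_ccg$t_range[2]
  span <- t1 - t0
  ctrl <- matrix(NA_real_, n_shuffles, length(raw_ccg$lags_ms))
  for (s in seq_len(n_shuffles)) {
    off <- stats::runif(1, 1, max(span - 1, 1.0001))
    sls <- ls
    sls$spike_times <- sort(((ls$spike_times - t0 + off) %% span) + t0)
    ctrl[s, ] <- cross_correlogram(hpc, sls, config, t_range = raw_ccg$t_range,
                                   normalization = raw_ccg$normalization)$raw
  }
  shuffle_mean <- mean(ctrl)
  corrected <- raw_ccg$raw - shuffle_mean
  structure(list(lags_ms = raw_ccg$lags_ms, raw = raw_ccg$raw,
                 corrected = corrected, shuffle_mean = shuffle_mean,
                 shuffle_sd = stats::sd(as.numeric(ctrl)),
                 mean_corrected = mean(corrected),
                 peak_lag_ms = raw_ccg$lags_ms[which.max(corrected)],
                 n_shuffles = n_shuffles, seed = seed,
                 normalization = raw_ccg$normalization,
                 hpc_unit = raw_ccg$hpc_unit, ls_unit = raw_ccg$ls_unit,
                 t_range = raw_ccg$t_range),
            class = "cross_correlogram")
}

#' Match HPC fields to LS fields by center proximity
#'
#' For each HPC field, LS fields whose centers lie within `match_radius`
#' (along-track, inclusive) are candidates; among candidates the LS field
#' whose unit mean rate is most similar to the HPC unit's is chosen
#' (distance breaks rate ties). Multi-field cells contribute one potential
#' match per field; unmatched fields are excluded.
#'
#' @param hpc_fields,ls_fields lists of `place_field`
#' @param unit_rates named vector of speed-filtered mean rates (Hz) per unit
#' @param maze a `maze_geometry`
#' @param config an `analysis_config`
#' @return data.frame: hpc_unit, ls_unit, hpc_center, ls_center,
#'   center_distance, rate_difference, arm_group (forced/middle/choice by
#'   the HPC field center)
#' @export
match_pairs <- function(hpc_fields, ls_fields, unit_rates, maze,
                        config = analysis_config()) {
  if (!length(hpc_fields) || !length(ls_fields))
    return(data.frame(hpc_unit = character(0), ls_unit = character(0),
                      hpc_center = numeric(0), ls_center = numeric(0),
                      center_distance = numeric(0), rate_difference = numeric(0),
                      arm_group = character(0)))
  ls_centers <- vapply(ls_fields, function(f) f$center_lin, numeric(1))
  rows <- list()
  for (f in hpc_fields) {
    dists <- path_distance(f$center_lin, ls_centers, maze)
    cand <- which(dists <= config$match_radius)
    if (!length(cand)) next
    rdiff <- abs(unit_rates[vapply(ls_fields[cand], function(g) g$unit_id, character(1))] -
                 unit_rates[f$unit_id])
    best <- cand[order(rdiff, dists[cand])][1]
    pa <- .lin_to_arm(f$center_lin, maze)
    grp <- switch(pa$arm, forced_left = , forced_right = "forced",
                  stem = "middle", choice_left = , choice_right = "choice")
    rows[[length(rows) + 1]] <- data.frame(
      hpc_unit = f$unit_id, ls_unit = ls_fields[[best]]$unit_id,
      hpc_center = f$center_lin, ls_center = ls_centers[best],
      center_distance = dists[best],
      rate_difference = unname(rdiff[order(rdiff, dists[cand])[1]]),
      arm_group = grp, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(match_pairs(list(), list(), unit_rates, maze, config))
  do.call(rbind, rows)
}

#' Summarize corrected correlations by maze arm
#'
#' Per-pair mean corrected correlation over the +/-100 ms lag range and peak
#' lag, grouped by the arm of the HPC field center, with group means, SEs,
#' mean peak lags, and pairwise two-sample t-tests between arm groups.
#'
#' @param pairs output of [match_pairs()]
#' @param ccgs list of `cross_correlogram`, parallel to `pairs` rows
#' @return list with `per_pair`, `groups` (arm_group, n, mean_corr, se_corr,
#'   mean_peak_lag_ms), and `tests` (pairwise pooled t-tests)
#' @export
summarize_pairs <- function(pairs, ccgs) {
  stopifnot(nrow(pairs) == length(ccgs))
  per_pair <- cbind(pairs,
                    mean_corr = vapply(ccgs, function(c) c$mean_corrected, numeric(1)),
                    peak_lag_ms = vapply(ccgs, function(c) c$peak_lag_ms, numeric(1)))
  grps <- split(per_pair, per_pair$arm_group)
  if (!length(grps)) stop("no matched pairs to summarize")
  groups <- do.call(rbind, lapply(names(grps), function(g) {
    v <- grps[[g]]$mean_corr
    data.frame(arm_group = g, n = length(v), mean_corr = mean(v),
               se_corr = stats::sd(v) / sqrt(length(v)),
               mean_peak_lag_ms = mean(grps[[g]]$peak_lag_ms),
               stringsAsFactors = FALSE)
  }))
  combs <- if (length(grps) >= 2) utils::combn(names(grps), 2) else NULL
  tests <- NULL
  if (!is.null(combs)) {
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- grps[[combs[1, i]]]$mean_corr; b <- grps[[combs[2, i]]]$mean_corr
      if (length(a) < 2 || length(b) < 2)
        return(data.frame(group_a = combs[1, i], group_b = combs[2, i],
                          statistic = NA_real_, df = NA_real_, p = NA_real_))
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(group_a = combs[1, i], group_b = combs[2, i],
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(per_pair = per_pair, groups = groups, tests = tests)
}

#' Correlations by session third
#'
#' Re-runs the correlogram pipeline with the analysis window restricted to
#' the first, middle, and last thirds of the session (half-open partition).
#' A pair is dropped for a third if either train has fewer than 2 spikes
#' there.
#'
#' @param pairs output of [match_pairs()]
#' @param sess a `session`
#' @param trains named list of `spike_train` by unit id
#' @param config an `analysis_config`
#' @param seed RNG seed for the shuffles
#' @return data.frame: third, hpc_unit, ls_unit, arm_group, mean_corr,
#'   peak_lag_ms
#' @export
session_thirds <- function(pairs, sess, trains, config = analysis_config(),
                           seed = 1) {
  cuts <- sess$t0 + sess$duration * c(0, 1, 2, 3) / 3
  rows <- list()
  for (third in 1:3) {
    tr_range <- c(cuts[third], cuts[third + 1])
    for (i in seq_len(nrow(pairs))) {
      h <- trains[[pairs$hpc_unit[i]]]; l <- trains[[pairs$ls_unit[i]]]
      hs <- h$spike_times[h$spike_times >= tr_range[1] & h$spike_times < tr_range[2]]
      lss <- l$spike_times[l$spike_times >= tr_range[1] & l$spike_times < tr_range[2]]
      if (length(hs) < 2 || length(lss) < 2) next
      h2 <- h; h2$spike_times <- hs
      l2 <- l; l2$spike_times <- lss
      raw <- cross_correlogram(h2, l2, config, t_range = tr_range)
      cc <- shuffle_correct(raw, h2, l2, config, seed = child_seed(seed, third * 1000 + i))
      rows[[length(rows) + 1]] <- data.frame(
        third = third, hpc_unit = h$unit_id, ls_unit = l$unit_id,
        arm_group = pairs$arm_group[i], mean_corr = cc$mean_corrected,
        peak_lag_ms = cc$peak_lag_ms, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(third = integer(0), hpc_unit = character(0),
                      ls_unit = character(0), arm_group = character(0),
                      mean_corr = numeric(0), peak_lag_ms = numeric(0)))
  do.call(rbind, rows)
}
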