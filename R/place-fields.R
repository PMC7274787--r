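# Place-field detection and shape statistics on 2 cm rate maps.
#
# A field is a connected region of bins (maze-graph adjacency: consecutive
# bins within an arm plus junction-crossing links) where the smoothed rate is
# at least one SD above the unit's mean map rate, containing at least one bin
# two SDs above, with linearized extent of at least 15 cm. The mean and SD
# are taken over the unit's smoothed rate-map values on visited bins.

# connected components of a bin subset under the grid adjacency
.components <- function(members, adj) {
  comps <- list()
  inset <- logical(length(adj)); inset[members] <- TRUE
  seen <- logical(length(adj))
  for (s in members) {
    if (seen[s]) next
    comp <- integer(0); stack <- s; seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (inset[w] && !seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Detect place fields on a rate map
#'
#' @param rm a `rate_map` on the field-analysis grid (2 cm bins by default)
#' @param config an `analysis_config`
#' @param direction optional direction label carried onto the fields
#' @return list of `place_field` objects (possibly empty). Each field has
#'   `bins`, `center_bin`, `center_lin` (cm), `length` (cm), `peak_rate`,
#'   `mu`, `sigma`, `unit_id`, `direction`. If the unit's maximum map rate is
#'   below the rate floor the unit is excluded (empty list, attribute
#'   `excluded = "low_rate"`).
#' @export
detect_fields <- function(rm, config = analysis_config(), direction = "both") {
  if (abs(rm$bin_size - config$field_bin) > 1e-9)
    stop("rate map is not on the field-analysis grid (", config$field_bin, " cm bins)")
  v <- rm$visited
  if (max(rm$rate[v]) < config$rate_floor) {
    out <- list(); attr(out, "excluded") <- "low_rate"; return(out)
  }
  mu <- mean(rm$rate[v]); sigma <- stats::sd(rm$rate[v])
  if (!is.finite(sigma) || sigma <= 0) return(list())
  members <- which(v & rm$rate >= mu + sigma)
  if (!length(members)) return(list())
  comps <- .components(members, rm$grid$adj)
  fields <- list()
  for (comp in comps) {
    if (max(rm$rate[comp]) < mu + 2 * sigma) next
    len <- length(comp) * rm$bin_size
    if (len < config$min_field_len) next
    r <- rm$rate[comp]
    peak <- max(r)
    # tie-break: lowest linearized coordinate among equal maxima
    cand <- comp[r >= peak - 1e-12]
    cb <- cand[which.min(rm$grid$bins$center[cand])]
    fields[[length(fields) + 1]] <- structure(list(
      unit_id = rm$unit_id, bins = comp, center_bin = cb,
      center_lin = rm$grid$bins$center[cb], length = len,
      peak_rate = peak, mu = mu, sigma = sigma,
      direction = direction), class = "place_field")
  }
  fields
}

#' Field center (peak-rate bin)
#'
#' Argmax of the smoothed rate within the field; among ties the bin with the
#' lowest linearized coordinate is returned.
#'
#' @param field a `place_field`
#' @param rm its `rate_map`
#' @return list with `bin`, `lin` (cm), `arm`
#' @export
field_center <- function(field, rm) {
  r <- rm$rate[field$bins]
  cand <- field$bins[r >= max(r) - 1e-12]
  cb <- cand[which.min(rm$grid$bins$center[cand])]
  list(bin = cb, lin = rm$grid$bins$center[cb], arm = rm$grid$bins$arm[cb])
}

#' Build direction-split rate maps for one unit
#'
#' Splits the speed-filtered trajectory into toward-reward and away-from-
#' reward segments using the trial events, and builds a rate map from each.
#'
#' @param sess a `session`
#' @param unit a `spike_train` from the session
#' @param config an `analysis_config`
#' @param filt optional precomputed [speed_filter()] result for the session
#'   (positions filtered once; the unit is filtered here)
#' @return list with `toward` and `away`, each `list(rm, occ)` or NULL if a
#'   direction has no samples
#' @export
split_by_direction <- function(sess, unit, config = analysis_config(),
                               filt = NULL) {
  if (is.null(filt)) {
    kin <- compute_acceleration(compute_speed(sess$positions, config$speed_smooth_sd))
    filt <- speed_filter(sess$positions, kin, list(unit), config$speed_threshold,
                         sess$maze)
    ftrain <- filt$trains[[1]]
  } else {
    kin <- attr(filt, "kin")
    sv <- stats::approx(kin$timestamps, kin$speed, xout = unit$spike_times,
                        rule = 2)$y
    ftrain <- unit; ftrain$spike_times <- unit$spike_times[sv >= config$speed_threshold]
  }
  grid <- track_grid(sess$maze, config$field_bin)
  dir_pos <- .direction_labels(filt$positions$t, sess$events)
  dir_spk <- .direction_labels(ftrain$spike_times, sess$events)
  out <- list()
  for (d in c("toward", "away")) {
    fp <- filt$positions[!is.na(dir_pos) & dir_pos == d, , drop = FALSE]
    if (nrow(fp) == 0) { out[[d]] <- NULL; next }
    tr <- ftrain
    tr$spike_times <- ftrain$spike_times[!is.na(dir_spk) & dir_spk == d]
    occ <- occupancy_map(fp, grid)
    out[[d]] <- list(rm = rate_map(tr, fp, occ, config$map_smooth_sd),
                     occ = occ, fpos = fp)
  }
  out
}

#' Classify field directionality
#'
#' Fields detected in the toward and away maps of one unit are merged as
#' bidirectional when their centers are separated by less than the match
#' radius (strictly less than 20 cm by default); all others stay
#' unidirectional.
#'
#' @param fields_toward,fields_away lists of `place_field` from the two maps
#' @param maze a `maze_geometry`
#' @param radius cm (default 20)
#' @return list of fields with `direction` set to `"toward_reward"`,
#'   `"away_from_reward"`, or `"both"`; bidirectional pairs contribute one
#'   field per direction (both labeled `"both"`, linked by `pair_id`)
#' @export
classify_directionality <- function(fields_toward, fields_away, maze,
                                    radius = 20) {
  used_away <- logical(length(fields_away))
  out <- list()
  for (f in fields_toward) {
    sep <- vapply(fields_away, function(g)
      path_distance(f$center_lin, g$center_lin, maze), numeric(1))
    sep[used_away] <- Inf
    j <- if (length(sep)) which.min(sep) else integer(0)
    if (length(j) && sep[j] < radius) {
      used_away[j] <- TRUE
      f$direction <- "both"; g <- fields_away[[j]]; g$direction <- "both"
      pid <- length(out) + 1
      f$pair_id <- pid; g$pair_id <- pid
      out[[length(out) + 1]] <- f
      out[[length(out) + 1]] <- g
    } else {
      f$direction <- "toward_reward"
      out[[length(out) + 1]] <- f
    }
  }
  for (g in fields_away[!used_away]) {
    g$direction <- "away_from_reward"
    out[[length(out) + 1]] <- g
  }
  out
}

# contiguous passes of the animal through the field's bins
.field_traversals <- function(field, sess, unit, config, filt) {
  fp <- filt$positions
  grid2 <- track_grid(sess$maze, config$field_bin)
  b <- .grid_bin(grid2, fp$lin)
  inf <- !is.na(b) & b %in% field$bins
  # contiguous runs of in-field fast samples (allowing single-sample gaps
  # from dropouts would complicate entry/exit; runs are kept literal)
  r <- rle(inf)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 2)
  trav <- list()
  for (k in runs) {
    i0 <- starts[k]; i1 <- ends[k]
    entry <- fp$t[i0]; exit <- fp$t[i1]
    sp <- unit$spike_times[unit$spike_times >= entry & unit$spike_times <= exit]
    trav[[length(trav) + 1]] <- list(lap = length(trav) + 1, entry = entry,
                                     exit = exit, spikes = sp,
                                     idx = i0:i1)
  }
  trav
}

#' Lap-by-lap field stability
#'
#' For each pass through the field, the location of maximum spiking (2 cm
#' bins within the field) and its along-track distance from the mean of the
#' per-lap peak locations. Fields passed through fewer than `min_traversals`
#' times are excluded (returns NULL).
#'
#' @param field a `place_field`
#' @param sess a `session`
#' @param unit the field's `spike_train`
#' @param config an `analysis_config`
#' @param filt precomputed [speed_filter()] result (optional)
#' @param min_traversals minimum passes (default 15)
#' @return data.frame lap, n_spikes, peak_lin, dist_from_mean (cm), or NULL
#' @export
lap_stability <- function(field, sess, unit, config = analysis_config(),
                          filt = NULL, min_traversals = 15) {
  if (is.null(filt)) {
    kin <- compute_acceleration(compute_speed(sess$positions, config$speed_smooth_sd))
    filt <- speed_filter(sess$positions, kin, list(unit), config$speed_threshold,
                         sess$maze)
  }
  trav <- .field_traversals(field, sess, unit, config, filt)
  if (length(trav) < min_traversals) return(NULL)
  grid2 <- track_grid(sess$maze, config$field_bin)
  fp <- filt$positions
  peak_lin <- vapply(trav, function(tv) {
    if (!length(tv$spikes)) return(NA_real_)
    # spike -> nearest fast sample -> field bin
    idx <- findInterval(tv$spikes, fp$t, all.inside = TRUE)
    lin <- fp$lin[idx]
    b <- .grid_bin(grid2, lin)
    b <- b[!is.na(b) & b %in% field$bins]
    if (!length(b)) return(NA_real_)
    tb <- table(b)
    grid2$bins$center[as.integer(names(tb)[which.max(tb)])]
  }, numeric(1))
  keep <- !is.na(peak_lin)
  pl <- peak_lin[keep]
  mean_center <- mean(pl)
  data.frame(lap = seq_along(pl), n_spikes = vapply(trav[keep], function(t) length(t$spikes), numeric(1)),
             peak_lin = pl,
             dist_from_mean = vapply(pl, function(p) path_distance(p, mean_center, sess$maze), numeric(1)))
}

#' Place-field skew along the direction of travel
#'
#' The within-field firing-rate profile is taken along the linearized track
#' (width-averaging is implicit in the 1-D track maps), ordered along the
#' direction of travel (by decreasing distance to the contextual reward for
#' toward-travel, increasing for away-travel), and its weighted third
#' standardized moment is returned. Positive skew = mass shifted toward later
#' positions along travel.
#'
#' @param field a `place_field`
#' @param rm the direction-split `rate_map` the field was detected on
#' @param maze a `maze_geometry`
#' @param travel `"toward"` or `"away"`
#' @param reward_context `"left"`, `"right"`, or `"nearest"`
#' @return skew (dimensionless), NA if the profile has no variance
#' @export
field_skew <- function(field, rm, maze, travel = "toward",
                       reward_context = "nearest") {
  if (length(field$bins) < 3) return(NA_real_)
  centers <- rm$grid$bins$center[field$bins]
  dr <- distance_to_reward(centers, maze, context = reward_context)
  ord <- order(if (travel == "toward") -dr else dr)
  w <- rm$rate[field$bins][ord]
  x <- seq_along(ord) * rm$bin_size
  weighted_skewness(x, w)
}

#' Firing-rate asymmetry index
#'
#' Per traversal with at least two spikes, the in-field spikes are split at
#' the median spike (by count); F1 and F2 are the mean rates over the entry-
#' to-split and split-to-exit intervals, and the index is
#' (F1 - F2) / (F1 + F2), averaged across traversals. Always in [-1, 1];
#' near 0 for a constant within-field rate; negative when firing ramps up
#' through the field.
#'
#' @param traversals list of traversals (elements with `entry`, `exit`,
#'   `spikes`), e.g. built internally by [lap_stability()]
#' @return list with `frai` (mean) and `per_traversal`
#' @export
field_frai <- function(traversals) {
  vals <- vapply(traversals, function(tv) {
    n <- length(tv$spikes)
    if (n < 2) return(NA_real_)
    sp <- sort(tv$spikes)
    n1 <- floor(n / 2)
    t_mid <- (sp[n1] + sp[n1 + 1]) / 2
    d1 <- max(t_mid - tv$entry, 1e-9)
    d2 <- max(tv$exit - t_mid, 1e-9)
    f1 <- n1 / d1; f2 <- (n - n1) / d2
    if (f1 + f2 <= 0) return(NA_real_)
    (f1 - f2) / (f1 + f2)
  }, numeric(1))
  list(frai = mean(vals, na.rm = TRUE), per_traversal = vals)
}

#' Field traversals for one unit/field
#'
#' Public wrapper around the traversal finder so FRAI can be computed from a
#' session directly.
#' @inheritParams lap_stability
#' @return list of traversals (entry, exit, spikes)
#' @export
field_traversals <- function(field, sess, unit, config = analysis_config(),
                             filt = NULL) {
  if (is.null(filt)) {
    kin <- compute_acceleration(compute_speed(sess$positions, config$speed_smooth_sd))
    filt <- speed_filter(sess$positions, kin, list(unit), config$speed_threshold,
                         sess$maze)
  }
  .field_traversals(field, sess, unit, config, filt)
}

#' Speed/acceleration regression control
#'
#' Ordinary least squares of the per-bin firing rate on the bin's mean speed
#' and acceleration (with intercept); returns the coefficient of
#' determination. A high r-squared would indicate that apparent spatial
#' firing is explained by kinematic modulation.
#'
#' @param rm a `rate_map`
#' @param kin_map result of [kinematics_maps()] on the same grid
#' @return r-squared
#' @export
speed_accel_regression <- function(rm, kin_map) {
  v <- rm$visited & !is.na(kin_map$speed)
  if (sum(v) < 10) stop("need at least 10 visited bins")
  df <- data.frame(r = rm$rate[v], s = kin_map$speed[v], a = kin_map$accel[v])
  if (all(is.na(df$a)) || stats::var(df$a, na.rm = TRUE) == 0) {
    fit <- stats::lm(r ~ s, data = df)
  } else {
    fit <- stats::lm(r ~ s + a, data = df)
  }
  summary(fit)$r.squared
}
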