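# Field-location geometry: arm assignment, junction exclusion, and field
# probability as a function of along-track distance from reward.
# (Linearization and geodesic distances live in maze-geometry.R.)

#' Assign fields to maze regions
#'
#' Labels each field center as `forced_side`, `stem`, or `choice_side`;
#' centers within `junction_halfwidth` cm (along the track) of a T junction
#' are labeled `forced_point` / `choice_point` and flagged for exclusion from
#' arm tallies, since junction fields cannot be assigned to one arm.
#'
#' @param fields list of `place_field`
#' @param maze a `maze_geometry`
#' @param junction_halfwidth cm (default 10)
#' @return data.frame: unit_id, field_id, center_lin, arm, location,
#'   excluded_from_tally, distance_to_reward (nearest reward, cm), direction
#' @export
assign_field_locations <- function(fields, maze, junction_halfwidth = 10) {
  if (!length(fields)) {
    return(data.frame(unit_id = character(0), field_id = integer(0),
                      center_lin = numeric(0), arm = character(0),
                      location = character(0), excluded_from_tally = logical(0),
                      distance_to_reward = numeric(0), direction = character(0)))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    pa <- .lin_to_arm(f$center_lin, maze)
    nd <- .node_dists(pa$arm, pa$u, maze)
    loc <- if (nd$dF <= junction_halfwidth) "forced_point"
           else if (nd$dC <= junction_halfwidth) "choice_point"
           else switch(pa$arm,
                       forced_left = , forced_right = "forced_side",
                       stem = "stem",
                       choice_left = , choice_right = "choice_side")
    data.frame(unit_id = f$unit_id, field_id = i, center_lin = f$center_lin,
               arm = pa$arm, location = loc,
               excluded_from_tally = loc %in% c("forced_point", "choice_point"),
               distance_to_reward = distance_to_reward(f$center_lin, maze),
               direction = f$direction %||% "both",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Field probability as a function of distance from reward
#'
#' Histogram of field-center counts over along-track distance-to-reward bins,
#' normalized by the total number of fields, with a companion track-exposure
#' column counting how many field-grid track bins map into each distance bin,
#' so the probability can be normalized for maze geometry (two arms converge
#' at equal reward distance, so exposure is non-uniform).
#'
#' @param fields list of `place_field`
#' @param maze a `maze_geometry`
#' @param bin_width distance bin width, cm (default 10)
#' @param track_bin track bin size used for the exposure column, cm
#' @return data.frame: dist_lo, dist_hi, n_fields, field_fraction,
#'   track_bins, density_per_track_bin
#' @export
field_probability_by_distance <- function(fields, maze, bin_width = 10,
                                          track_bin = 2) {
  if (!length(fields)) stop("need at least one field")
  d <- vapply(fields, function(f) distance_to_reward(f$center_lin, maze),
              numeric(1))
  grid <- track_grid(maze, track_bin)
  dtrack <- distance_to_reward(grid$bins$center, maze)
  dmax <- max(dtrack) + bin_width
  edges <- seq(0, dmax, by = bin_width)
  if (edges[length(edges)] < dmax) edges <- c(edges, dmax)
  cut_idx <- findInterval(d, edges, rightmost.closed = TRUE)
  n <- tabulate(cut_idx, nbins = length(edges) - 1)
  exposure <- tabulate(findInterval(dtrack, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1)
  frac <- n / length(fields)
  data.frame(dist_lo = edges[-length(edges)], dist_hi = edges[-1],
             n_fields = n, field_fraction = frac, track_bins = exposure,
             density_per_track_bin = ifelse(exposure > 0, frac / exposure, NA_real_))
}

#' Arm tallies of field locations
#'
#' Counts fields on the forced sides, center stem, and choice sides,
#' excluding junction-labeled fields (the paper-style three-region tally).
#'
#' @param assignments output of [assign_field_locations()]
#' @return named vector of counts plus `excluded_junction`
#' @export
arm_tally <- function(assignments) {
  a <- assignments[!assignments$excluded_from_tally, , drop = FALSE]
  c(forced_side = sum(a$location == "forced_side"),
    stem = sum(a$location == "stem"),
    choice_side = sum(a$location == "choice_side"),
    excluded_junction = sum(assignments$excluded_from_tally))
}
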