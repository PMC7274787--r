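# Shared fixtures, built once per test run. The medium trajectory (40 trials,
# ~15 min) is reused by most map-level tests; per-test spike trains are
# generated on top of it with their own seeds.

fix_maze <- build_maze(100, 100)
fix_traj <- simulate_trajectory(fix_maze, n_trials = 40, seed = 7)
fix_kin <- compute_acceleration(compute_speed(fix_traj$positions, 1))
fix_grid1 <- track_grid(fix_maze, 1)
fix_grid2 <- track_grid(fix_maze, 2)
fix_filt <- speed_filter(fix_traj$positions, fix_kin, list(), 12, fix_maze)
fix_cfg <- analysis_config()

# a session around the shared trajectory with a given list of trains
fix_session <- function(trains) {
  suppressMessages(session(fix_traj$positions, trains, fix_maze,
                           events = fix_traj$events))
}

# maps for one spike train on the shared trajectory
fix_maps <- function(train, bin = 2, smooth = 10) {
  filt <- speed_filter(fix_traj$positions, fix_kin, list(train), 12, fix_maze)
  grid <- if (bin == 2) fix_grid2 else track_grid(fix_maze, bin)
  occ <- occupancy_map(filt$positions, grid)
  list(filt = filt, occ = occ,
       rm = rate_map(filt$trains[[1]], filt$positions, occ, smooth))
}

# a rate_map object holding an arbitrary noise-free profile on a grid
profile_rate_map <- function(values, grid, smooth = 0, unit_id = "prof") {
  v <- rep(TRUE, nrow(grid$bins))
  r <- if (smooth > 0) mazefields:::.smooth_masked(values, grid, v, smooth) else values
  structure(list(rate = r, rate_raw = values, mean_rate = mean(r),
                 visited = v, grid = grid, bin_size = grid$bin_size,
                 smooth_sd = smooth, unit_id = unit_id), class = "rate_map")
}

# minimal hand-built occupancy/rate map pair on a 1-D line (for the
# closed-form information tests, independent of maze machinery)
toy_maps <- function(P, R) {
  n <- length(P)
  grid <- structure(list(
    bins = data.frame(arm = "stem", lo = seq_len(n) - 1, hi = seq_len(n),
                      center = seq_len(n) - 0.5),
    adj = lapply(seq_len(n), function(i)
      setdiff(intersect(c(i - 1L, i + 1L), seq_len(n)), i)),
    D = abs(outer(seq_len(n), seq_len(n), "-")), bin_size = 1),
    class = "track_grid")
  occ <- structure(list(P = P, dwell = P, visited = P > 0, total_time = 1,
                        grid = grid, bin_size = 1), class = "occupancy_map")
  rm <- structure(list(rate = R, rate_raw = R, mean_rate = sum(P * R),
                       visited = P > 0, grid = grid, bin_size = 1,
                       smooth_sd = 0, unit_id = "toy"), class = "rate_map")
  list(occ = occ, rm = rm)
}

# expected (noise-free) smoothed rate map of a planted symmetric field,
# pushed through the same detector -- the ground-truth oracle for
# center/length recovery
truth_fields <- function(center, width_sd, peak, baseline = 0.1,
                         grid = fix_grid2, cfg = fix_cfg) {
  d <- path_distance(grid$bins$center, center, fix_maze)
  lam <- baseline + (peak - baseline) * exp(-d^2 / (2 * width_sd^2))
  detect_fields(profile_rate_map(lam, grid, smooth = cfg$map_smooth_sd), cfg)
}
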