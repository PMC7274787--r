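test_that("trajectory simulation is deterministic and honors dropouts", {
  t1 <- simulate_trajectory(fix_maze, n_trials = 6, seed = 11)
  t2 <- simulate_trajectory(fix_maze, n_trials = 6, seed = 11)
  expect_identical(t1$positions$timestamps, t2$positions$timestamps)
  expect_identical(t1$positions$x, t2$positions$x)
  expect_identical(t1$events, t2$events)
  expect_error(simulate_trajectory(fix_maze, n_trials = 0), "n_trials")
  expect_error(simulate_trajectory(fix_maze, dropout_frac = 1), "dropout_frac")
  # dropout 0.5 halves the 30 Hz sampling: median interval ~ 1/15 s
  expect_lt(abs(median(diff(t1$positions$timestamps)) - 1 / 15), 0.01)
  t0 <- simulate_trajectory(fix_maze, n_trials = 6, seed = 11, dropout_frac = 0)
  expect_lt(abs(median(diff(t0$positions$timestamps)) - 1 / 30), 0.005)
  # forced side never repeats more than three consecutive times
  long <- simulate_trajectory(fix_maze, n_trials = 60, seed = 12)
  sides <- long$events$arm[long$events$event == "trial_start"]
  runs <- rle(sides)$lengths
  expect_lte(max(runs), 3)
})

test_that("closed loop: kinematics recovers the simulated running speed", {
  tj <- simulate_trajectory(fix_maze, n_trials = 6, seed = 13, dropout_frac = 0,
                            speed_cv = 0, pos_noise_cm = 0)
  kin <- compute_speed(tj$positions, smooth_sd = 1)
  # on run segments away from pauses/turns the smoothed speed matches the
  # planted constant speed within 5%
  run <- kin$speed > 12
  med <- median(kin$speed[run])
  expect_lt(abs(med - 35) / 35, 0.05)
})

test_that("homogeneous Poisson units match their analytic law", {
  expect_length(generate_poisson_unit(0, 1000, seed = 1)$spike_times, 0)
  expect_error(generate_poisson_unit(-1, 10), "mean_rate")
  tr <- generate_poisson_unit(5, 1800, seed = 2)
  n <- length(tr$spike_times)
  expect_lt(abs(n - 9000), 3 * sqrt(9000))
  # ISI distribution is exponential(rate)
  ps <- vapply(1:3, function(s) {
    isi <- diff(generate_poisson_unit(5, 1800, seed = 10 + s)$spike_times)
    suppressWarnings(stats::ks.test(isi, "pexp", 5)$p.value)
  }, numeric(1))
  expect_true(all(ps > 0.005))
  # determinism
  expect_identical(generate_poisson_unit(5, 100, seed = 3)$spike_times,
                   generate_poisson_unit(5, 100, seed = 3)$spike_times)
})

test_that("place-cell generator plants fields where it says", {
  expect_error(field_spec(100, -1, 5), "width_sd")
  expect_error(field_spec(100, 5, 1, baseline_rate = 2), "peak_rate")
  # a silent spec produces an empty train
  fs0 <- field_spec(250, 10, 0, baseline_rate = 0)
  expect_length(generate_place_cell(fs0, fix_traj, fix_maze, seed = 1)$spike_times, 0)
  # spikes concentrate near the planted center
  fs <- field_spec(250, 8, 12, 0.1, 0, "both")
  tr <- generate_place_cell(fs, fix_traj, fix_maze, seed = 5)
  expect_gt(length(tr$spike_times), 100)
  pc <- pos_cm(fix_traj$positions)
  lp <- linearize(pc$x, pc$y, fix_maze)
  idx <- findInterval(tr$spike_times, pc$t, all.inside = TRUE)
  d <- path_distance(lp$lin[idx], 250, fix_maze)
  expect_gt(mean(d < 25), 0.8)
  # direction gating: a toward-only cell is silent during away travel
  fst <- field_spec(250, 8, 12, 0, 0, "toward_reward")
  trt <- generate_place_cell(fst, fix_traj, fix_maze, seed = 6)
  lab <- mazefields:::.direction_labels(trt$spike_times, fix_traj$events)
  expect_true(all(lab[!is.na(lab)] == "toward"))
})

test_that("coupled pairs relay HPC spikes at the configured lag", {
  expect_error(coupling_spec(transmission_prob = 1.5), "transmission_prob")
  fs <- field_spec(250, 10, 10, 0.2, 0, "both")
  # prob 1, jitter 0, background 0: LS is exactly HPC shifted by the lag
  pr <- generate_coupled_pair(fs, coupling_spec(20, 1, 0, 0), fix_traj,
                              fix_maze, seed = 8)
  keep <- pr$hpc$spike_times + 0.02 <= max(fix_traj$positions$timestamps)
  expect_equal(pr$ls$spike_times, (pr$hpc$spike_times + 0.02)[keep])
  # prob 0: the LS train is pure background, independent of the HPC spec
  fs2 <- field_spec(50, 10, 10, 0.2, 0, "both")
  pa <- generate_coupled_pair(fs, coupling_spec(20, 0, 0, 2), fix_traj,
                              fix_maze, seed = 9)
  pb <- generate_coupled_pair(fs2, coupling_spec(20, 0, 0, 2), fix_traj,
                              fix_maze, seed = 9)
  expect_identical(pa$ls$spike_times, pb$ls$spike_times)
})

test_that("full synthetic sessions are deterministic with serializable truth", {
  spec <- synthetic_spec(n_hpc_place = 3, n_ls_place = 2, n_pairs = 1,
                         n_kinematic = 1, n_poisson = 2, n_trials = 6)
  g1 <- suppressMessages(generate_session(spec, seed = 31))
  expect_length(g1$session$trains,
                3 + 2 + 2 * 1 + 1 + 2)
  expect_equal(length(g1$truth$units), length(g1$session$trains))
  expect_length(g1$truth$pairs, 1)
  # same seed: byte-identical written sessions
  dir <- withr::local_tempdir()
  g2 <- suppressMessages(generate_session(spec, seed = 31))
  write_session(g1$session, file.path(dir, "a"))
  write_session(g2$session, file.path(dir, "b"))
  for (f in list.files(file.path(dir, "a"))) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)), label = f)
  }
  # ground truth serializes to JSON and back
  j <- jsonlite::toJSON(g1$truth, auto_unbox = TRUE, digits = NA)
  tr <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_equal(tr$seed, 31)
  expect_equal(length(tr$units), length(g1$truth$units))
})
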