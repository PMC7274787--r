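# Synthetic session generator with planted ground truth.
#
# Emulates a rewarded double-sided T-maze session: trajectories with
# reward-site pauses and tracking dropouts, inhomogeneous-Poisson place cells
# with a skewable field profile, homogeneous Poisson control units,
# speed/acceleration-modulated non-place units, and HPC->LS coupled pairs with
# a configurable transmission lag. Every generator is deterministic under its
# seed, so downstream stages can be scored against the planted parameters.

#' Place-field specification for a synthetic unit
#'
#' @param center field center, global linearized track cm
#' @param width_sd field width (SD of the bump), cm
#' @param peak_rate peak firing rate, Hz
#' @param baseline_rate out-of-field rate, Hz
#' @param skew_shape signed shape parameter of the skew-normal bump; 0 gives a
#'   symmetric field, positive values shift mass toward later positions along
#'   the direction of travel
#' @param direction `"toward_reward"`, `"away_from_reward"`, or `"both"`
#' @export
field_spec <- function(center, width_sd, peak_rate, baseline_rate = 0.1,
                       skew_shape = 0, direction = "both") {
  direction <- match.arg(direction, c("toward_reward", "away_from_reward", "both"))
  if (width_sd <= 0) stop("width_sd must be > 0")
  silent <- peak_rate == 0 && baseline_rate == 0
  if (!silent && !(peak_rate > baseline_rate && baseline_rate >= 0))
    stop("need peak_rate > baseline_rate >= 0")
  structure(list(center = center, width_sd = width_sd, peak_rate = peak_rate,
                 baseline_rate = baseline_rate, skew_shape = skew_shape,
                 direction = direction), class = "field_spec")
}

#' HPC-to-LS coupling specification
#'
#' @param lag_ms transmission lag, ms (positive: LS follows HPC)
#' @param transmission_prob probability an HPC spike is relayed
#' @param jitter_sd_ms Gaussian jitter on the relayed spike, ms
#' @param ls_background_rate independent LS background rate, Hz
#' @export
coupling_spec <- function(lag_ms = 20, transmission_prob = 0.3,
                          jitter_sd_ms = 2, ls_background_rate = 2) {
  if (transmission_prob < 0 || transmission_prob > 1)
    stop("transmission_prob must be in [0, 1]")
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be >= 0")
  structure(list(lag_ms = lag_ms, transmission_prob = transmission_prob,
                 jitter_sd_ms = jitter_sd_ms,
                 ls_background_rate = ls_background_rate),
            class = "coupling_spec")
}

.rtruncnorm1 <- function(n, mean, sd, lo) pmax(stats::rnorm(n, mean, sd), lo)

#' Simulate a T-maze trajectory
#'
#' Generates 30 Hz position samples following forced-arm -> stem -> choice-arm
#' runs with a pause at the visited reward site, then the mirrored return to
#' the next forced arm. The forced side is drawn uniformly with the constraint
#' that the same side is never forced more than three consecutive times; the
#' choice is correct (rewarded) with probability `p_correct`. Leg speeds are
#' drawn from a truncated normal (floor 1 cm/s); reward pauses sit well below
#' the 12 cm/s filter so the speed filter is exercised. Interior samples are
#' deleted independently with probability `dropout_frac`, emulating camera
#' occlusion.
#'
#' @param maze a `maze_geometry`
#' @param n_trials number of trials (>= 1)
#' @param speed_mean mean running speed, cm/s
#' @param pause_s pause duration at the reward site, s
#' @param dropout_frac fraction of samples dropped, in [0, 1)
#' @param seed RNG seed
#' @param px_per_cm pixel conversion used for the emitted pixel coordinates
#' @param p_correct probability of a correct (rewarded) choice
#' @param pos_noise_cm isotropic tracking noise SD, cm
#' @param speed_cv coefficient of variation of the per-leg running speed
#'   (0 gives constant-speed legs)
#' @return list with `positions` (a `position_series`) and `events`
#'   (data.frame: time, event, arm, correct)
#' @export
simulate_trajectory <- function(maze, n_trials = 40, speed_mean = 35,
                                pause_s = 5, dropout_frac = 0.5, seed = 1,
                                px_per_cm = 3.2, p_correct = 0.75,
                                pos_noise_cm = 0.25, speed_cv = 0.15) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (dropout_frac >= 1 || dropout_frac < 0) stop("dropout_frac must be in [0, 1)")
  set.seed(seed)
  dt <- 1 / 30
  A <- maze$arm_length; S <- maze$stem_length
  arm_xy <- function(arm, u) {
    a <- maze$arms[maze$arms$label == arm, ]
    frac <- u / a$length
    c(a$x0 + frac * (a$x1 - a$x0), a$y0 + frac * (a$y1 - a$y0))
  }
  # forced side sequence: uniform, never the same side more than 3x in a row
  sides <- character(n_trials)
  for (k in seq_len(n_trials)) {
    if (k > 3 && length(unique(sides[(k - 3):(k - 1)])) == 1) {
      sides[k] <- setdiff(c("left", "right"), sides[k - 1])
    } else sides[k] <- sample(c("left", "right"), 1)
  }
  correct <- stats::runif(n_trials) < p_correct
  ts <- xs <- ys <- numeric(0)
  ev <- list()
  t_now <- 0
  emit_leg <- function(arm, u_from, u_to, t_start) {
    len <- abs(u_to - u_from)
    v <- .rtruncnorm1(1, speed_mean, speed_cv * speed_mean, 1)
    dur <- len / v
    tt <- seq(0, dur, by = dt)
    uu <- u_from + (u_to - u_from) * tt / dur
    xy <- vapply(uu, function(u) arm_xy(arm, u), numeric(2))
    list(t = t_start + tt, x = xy[1, ], y = xy[2, ], t_end = t_start + dur)
  }
  emit_pause <- function(arm, u, t_start, dur) {
    tt <- seq(0, dur, by = dt)
    xy <- arm_xy(arm, u)
    # slow jitter around the site (well under the speed filter)
    list(t = t_start + tt,
         x = xy[1] + cumsum(stats::rnorm(length(tt), 0, 0.05)),
         y = xy[2] + cumsum(stats::rnorm(length(tt), 0, 0.05)),
         t_end = t_start + dur)
  }
  add <- function(seg) {
    ts <<- c(ts, seg$t); xs <<- c(xs, seg$x); ys <<- c(ys, seg$y)
    t_now <<- seg$t_end + dt
  }
  for (k in seq_len(n_trials)) {
    forced_arm <- paste0("forced_", sides[k])
    choice_side <- if (correct[k]) sides[k] else setdiff(c("left", "right"), sides[k])
    choice_arm <- paste0("choice_", choice_side)
    ev[[length(ev) + 1]] <- data.frame(time = t_now, event = "trial_start",
                                       arm = forced_arm, correct = correct[k])
    add(emit_leg(forced_arm, A, 0, t_now))       # forced arm inbound
    add(emit_leg("stem", 0, S, t_now))           # stem F -> C
    add(emit_leg(choice_arm, 0, A, t_now))       # choice arm outbound
    ev[[length(ev) + 1]] <- data.frame(time = t_now, event = "choice_arrival",
                                       arm = choice_arm, correct = correct[k])
    if (correct[k])
      ev[[length(ev) + 1]] <- data.frame(time = t_now, event = "reward",
                                         arm = choice_arm, correct = TRUE)
    add(emit_pause(choice_arm, A, t_now, if (correct[k]) pause_s else pause_s / 3))
    # return run toward the next trial's forced arm
    next_forced <- paste0("forced_", sides[min(k + 1, n_trials)])
    add(emit_leg(choice_arm, A, 0, t_now))
    add(emit_leg("stem", S, 0, t_now))
    add(emit_leg(next_forced, 0, A, t_now))
    add(emit_pause(next_forced, A, t_now, 0.5))
  }
  xs <- xs + stats::rnorm(length(xs), 0, pos_noise_cm)
  ys <- ys + stats::rnorm(length(ys), 0, pos_noise_cm)
  keep <- c(TRUE, stats::runif(length(ts) - 2) >= dropout_frac, TRUE)
  pos <- position_series(ts[keep] - ts[1], xs[keep] * px_per_cm,
                         ys[keep] * px_per_cm, px_per_cm = px_per_cm,
                         nominal_rate = 30)
  events <- do.call(rbind, ev)
  events$time <- events$time - ts[1]
  list(positions = pos, events = events)
}

# per-sample travel-direction labels from trial events:
# toward reward between trial_start and choice_arrival, away afterwards
.direction_labels <- function(times, events) {
  if (is.null(events) || !any(events$event == "choice_arrival"))
    stop("session has no reward/arrival events; cannot label travel direction")
  lab <- rep(NA_character_, length(times))
  starts <- events$time[events$event == "trial_start"]
  arrivals <- events$time[events$event == "choice_arrival"]
  marks <- rbind(data.frame(t = starts, l = "toward"),
                 data.frame(t = arrivals, l = "away"))
  marks <- marks[order(marks$t), ]
  idx <- findInterval(times, marks$t)
  ok <- idx >= 1
  lab[ok] <- marks$l[idx[ok]]
  lab
}

# contextual reward for each sample: the chosen arm's reward while heading
# toward it, the just-visited reward on the way back
.reward_context <- function(times, events) {
  arr <- events[events$event == "choice_arrival", ]
  side <- sub("choice_", "", arr$arm)
  # context switches at trial starts (next target) and is the visited side
  # from arrival onward; approximate the target by the eventual arrival side
  starts <- events$time[events$event == "trial_start"]
  marks <- data.frame(t = starts, side = side[seq_along(starts)])
  idx <- findInterval(times, marks$t)
  ctx <- rep(NA_character_, length(times))
  ok <- idx >= 1
  ctx[ok] <- marks$side[idx[ok]]
  ctx
}

# signed along-travel coordinate of each sample relative to a field center:
# magnitude is the true geodesic distance to the center; the sign says
# whether the animal is past the center in the direction of travel (judged by
# comparing reward distances in the trial's reward context)
.signed_field_dist <- function(lin, dir_lab, ctx, center, maze) {
  d <- rep(NA_real_, length(lin))
  mag <- path_distance(lin, center, maze)
  for (side in c("left", "right")) {
    sel <- which(ctx == side)
    if (!length(sel)) next
    dr <- distance_to_reward(lin[sel], maze, context = side)
    dc <- distance_to_reward(center, maze, context = side)
    toward <- dir_lab[sel] == "toward"
    past <- ifelse(toward, dr <= dc, dr > dc)
    d[sel] <- ifelse(past, mag[sel], -mag[sel])
  }
  d
}

# unit-peak skew-normal bump profile
.bump <- function(d, width_sd, skew_shape) {
  z <- d / width_sd
  f <- exp(-z^2 / 2) * stats::pnorm(skew_shape * z)
  zg <- seq(-6, 6, by = 0.01)
  fmax <- max(exp(-zg^2 / 2) * stats::pnorm(skew_shape * zg))
  f / fmax
}

#' Generate an inhomogeneous-Poisson place cell
#'
#' The rate is `baseline + (peak - baseline) * g(d(t))` where `d(t)` is the
#' signed along-track distance of the animal from the field center, oriented
#' along the direction of travel, and `g` is a unit-peak skew-normal bump
#' (`skew_shape` shifts mass toward positive `d`). For unidirectional specs
#' the bump is gated off when travel direction does not match. Spikes are
#' drawn by thinning a homogeneous Poisson train at the peak rate.
#'
#' @param spec a `field_spec`
#' @param traj result of [simulate_trajectory()] (positions + events)
#' @param maze a `maze_geometry`
#' @param seed RNG seed
#' @param unit_id,region identity of the emitted train
#' @return a `spike_train`
#' @export
generate_place_cell <- function(spec, traj, maze, seed = 1, unit_id = "u1",
                                region = "HPC") {
  pos <- traj$positions
  if (!length(pos$timestamps)) stop("trajectory is empty")
  set.seed(seed)
  pc <- pos_cm(pos)
  lp <- linearize(pc$x, pc$y, maze)
  dir_lab <- .direction_labels(pc$t, traj$events)
  ctx <- .reward_context(pc$t, traj$events)
  d <- .signed_field_dist(lp$lin, dir_lab, ctx, spec$center, maze)
  lam <- rep(spec$baseline_rate, nrow(pc))
  ok <- !is.na(d)
  gate <- switch(spec$direction,
                 both = rep(TRUE, nrow(pc)),
                 toward_reward = dir_lab == "toward",
                 away_from_reward = dir_lab == "away")
  gate[is.na(gate)] <- FALSE
  sel <- ok & gate
  lam[sel] <- spec$baseline_rate +
    (spec$peak_rate - spec$baseline_rate) * .bump(d[sel], spec$width_sd, spec$skew_shape)
  if (spec$peak_rate <= 0) {
    return(spike_train(unit_id, region, numeric(0)))
  }
  t0 <- pc$t[1]; t1 <- pc$t[nrow(pc)]
  n_cand <- stats::rpois(1, spec$peak_rate * (t1 - t0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  lam_at <- stats::approx(pc$t, lam, xout = cand, rule = 2)$y
  keep <- stats::runif(n_cand) < lam_at / spec$peak_rate
  spike_train(unit_id, region, cand[keep])
}

#' Generate a homogeneous Poisson unit
#'
#' @param mean_rate Hz (>= 0)
#' @param duration s
#' @param seed RNG seed
#' @param unit_id,region identity of the emitted train
#' @export
generate_poisson_unit <- function(mean_rate, duration, seed = 1,
                                  unit_id = "p1", region = "LS") {
  if (mean_rate < 0) stop("mean_rate must be >= 0")
  set.seed(seed)
  n <- stats::rpois(1, mean_rate * duration)
  spike_train(unit_id, region, sort(stats::runif(n, 0, duration)))
}

#' Generate a speed/acceleration-modulated non-place unit
#'
#' Rate is a rectified linear function of instantaneous speed and
#' acceleration, emulating kinematic (non-spatial) septal units.
#'
#' @param traj trajectory (positions + events)
#' @param base_rate Hz at mean kinematics
#' @param speed_gain Hz per (cm/s), applied to speed deviations from its mean
#' @param accel_gain Hz per (cm/s^2)
#' @param seed RNG seed
#' @param unit_id,region identity of the emitted train
#' @export
generate_kinematic_unit <- function(traj, base_rate = 5, speed_gain = 0.1,
                                    accel_gain = 0, seed = 1,
                                    unit_id = "k1", region = "LS") {
  set.seed(seed)
  kin <- compute_speed(traj$positions, smooth_sd = 1)
  kin <- compute_acceleration(kin)
  lam <- pmax(0, base_rate + speed_gain * (kin$speed - mean(kin$speed)) +
                accel_gain * kin$acceleration)
  lmax <- max(lam)
  if (lmax <= 0) return(spike_train(unit_id, region, numeric(0)))
  t0 <- kin$timestamps[1]; t1 <- kin$timestamps[length(kin$timestamps)]
  n_cand <- stats::rpois(1, lmax * (t1 - t0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  lam_at <- stats::approx(kin$timestamps, lam, xout = cand, rule = 2)$y
  keep <- stats::runif(n_cand) < lam_at / lmax
  spike_train(unit_id, region, cand[keep])
}

#' Generate an HPC place cell and a coupled LS unit
#'
#' The LS train is the union of an independent Poisson background and, for
#' each HPC spike, a relayed spike at `lag_ms` (+ Gaussian jitter) kept with
#' probability `transmission_prob`.
#'
#' @param hpc_spec a `field_spec` for the HPC member
#' @param coupling a `coupling_spec`
#' @param traj trajectory (positions + events)
#' @param maze a `maze_geometry`
#' @param seed RNG seed
#' @param hpc_id,ls_id unit ids
#' @return list of two `spike_train`s (`hpc`, `ls`)
#' @export
generate_coupled_pair <- function(hpc_spec, coupling, traj, maze, seed = 1,
                                  hpc_id = "hpc1", ls_id = "ls1") {
  hpc <- generate_place_cell(hpc_spec, traj, maze, seed = seed,
                             unit_id = hpc_id, region = "HPC")
  set.seed(child_seed(seed, 1))
  t0 <- traj$positions$timestamps[1]
  t1 <- traj$positions$timestamps[length(traj$positions$timestamps)]
  nbg <- stats::rpois(1, coupling$ls_background_rate * (t1 - t0))
  bg <- stats::runif(nbg, t0, t1)
  relayed <- hpc$spike_times + coupling$lag_ms / 1000 +
    stats::rnorm(length(hpc$spike_times), 0, coupling$jitter_sd_ms / 1000)
  keep <- stats::runif(length(relayed)) < coupling$transmission_prob
  ls_times <- sort(c(bg, relayed[keep]))
  ls_times <- ls_times[ls_times >= t0 & ls_times <= t1]
  list(hpc = hpc, ls = spike_train(ls_id, "LS", ls_times))
}

#' Default synthetic-session specification
#'
#' The conditions a typical recording session presents to the pipeline:
#' a 100 cm-armed maze, 40 trials (~20 min of running), 12 HPC place cells
#' and 8 LS place cells with centers spread over the track (LS centers biased
#' 2:1 toward the choice arms), widths 5-15 cm SD, peaks 5-15 Hz, a mix of
#' skews and directionalities, 4 HPC->LS coupled pairs at a 20 ms lag, 6
#' kinematic LS units, and 4 low-rate Poisson units per region.
#'
#' @param n_hpc_place,n_ls_place,n_pairs,n_kinematic,n_poisson population sizes
#' @param n_trials trials for the trajectory
#' @param lag_ms coupling lag for the planted pairs
#' @export
synthetic_spec <- function(n_hpc_place = 12, n_ls_place = 8, n_pairs = 4,
                           n_kinematic = 6, n_poisson = 4, n_trials = 40,
                           lag_ms = 20) {
  list(arm_length = 100, stem_length = 100, n_trials = n_trials,
       speed_mean = 35, pause_s = 5, dropout_frac = 0.5,
       n_hpc_place = n_hpc_place, n_ls_place = n_ls_place,
       n_pairs = n_pairs, n_kinematic = n_kinematic, n_poisson = n_poisson,
       width_sd_range = c(5, 15), peak_range = c(5, 15),
       baseline_range = c(0.05, 0.3), skew_range = c(-3, 3),
       coupling = coupling_spec(lag_ms = lag_ms, transmission_prob = 0.3,
                                jitter_sd_ms = 2, ls_background_rate = 2))
}

.draw_field_spec <- function(spec, maze, region) {
  # LS centers biased 2:1 toward choice arms, HPC uniform over the track
  if (region == "LS" && stats::runif(1) < 2 / 3) {
    arm <- sample(c("choice_left", "choice_right"), 1)
    off <- maze$arms$offset[maze$arms$label == arm]
    center <- off + stats::runif(1, 0, maze$arm_length)
  } else {
    center <- stats::runif(1, 0, maze$total_length)
  }
  field_spec(center = center,
             width_sd = stats::runif(1, spec$width_sd_range[1], spec$width_sd_range[2]),
             peak_rate = stats::runif(1, spec$peak_range[1], spec$peak_range[2]),
             baseline_rate = stats::runif(1, spec$baseline_range[1], spec$baseline_range[2]),
             skew_shape = stats::runif(1, spec$skew_range[1], spec$skew_range[2]),
             direction = sample(c("toward_reward", "away_from_reward", "both"),
                                1, prob = c(0.35, 0.25, 0.4)))
}

#' Generate a complete synthetic session with ground truth
#'
#' @param spec a specification list from [synthetic_spec()]
#' @param seed RNG seed; the session is fully determined by (spec, seed)
#' @return list with `session` (a `session`) and `truth` (planted unit specs,
#'   coupled pairs, and the seed; JSON-serializable)
#' @export
generate_session <- function(spec = synthetic_spec(), seed = 1) {
  maze <- build_maze(spec$arm_length, spec$stem_length)
  traj <- simulate_trajectory(maze, n_trials = spec$n_trials,
                              speed_mean = spec$speed_mean,
                              pause_s = spec$pause_s,
                              dropout_frac = spec$dropout_frac,
                              seed = child_seed(seed, 0))
  dur <- diff(range(traj$positions$timestamps))
  set.seed(child_seed(seed, 99))
  trains <- list(); truth_units <- list(); truth_pairs <- list()
  k <- 0
  add_unit <- function(tr, info) {
    trains[[length(trains) + 1]] <<- tr
    info$unit_id <- tr$unit_id; info$region <- tr$region
    truth_units[[length(truth_units) + 1]] <<- info
  }
  for (i in seq_len(spec$n_hpc_place)) {
    k <- k + 1
    fs <- .draw_field_spec(spec, maze, "HPC")
    add_unit(generate_place_cell(fs, traj, maze, seed = child_seed(seed, k),
                                 unit_id = sprintf("hpc_pc%02d", i), region = "HPC"),
             c(list(type = "place"), unclass(fs)))
  }
  for (i in seq_len(spec$n_ls_place)) {
    k <- k + 1
    fs <- .draw_field_spec(spec, maze, "LS")
    add_unit(generate_place_cell(fs, traj, maze, seed = child_seed(seed, k),
                                 unit_id = sprintf("ls_pc%02d", i), region = "LS"),
             c(list(type = "place"), unclass(fs)))
  }
  for (i in seq_len(spec$n_pairs)) {
    k <- k + 1
    fs <- .draw_field_spec(spec, maze, "HPC")
    pr <- generate_coupled_pair(fs, spec$coupling, traj, maze,
                                seed = child_seed(seed, k),
                                hpc_id = sprintf("hpc_cp%02d", i),
                                ls_id = sprintf("ls_cp%02d", i))
    add_unit(pr$hpc, c(list(type = "place"), unclass(fs)))
    add_unit(pr$ls, list(type = "coupled", partner = pr$hpc$unit_id,
                         lag_ms = spec$coupling$lag_ms,
                         transmission_prob = spec$coupling$transmission_prob))
    truth_pairs[[length(truth_pairs) + 1]] <-
      c(list(hpc = pr$hpc$unit_id, ls = pr$ls$unit_id), unclass(spec$coupling))
  }
  for (i in seq_len(spec$n_kinematic)) {
    k <- k + 1
    g <- stats::runif(1, 0.05, 0.2)
    add_unit(generate_kinematic_unit(traj, base_rate = stats::runif(1, 2, 8),
                                     speed_gain = g, accel_gain = stats::runif(1, 0, 0.1),
                                     seed = child_seed(seed, k),
                                     unit_id = sprintf("ls_kin%02d", i), region = "LS"),
             list(type = "kinematic", speed_gain = g))
  }
  for (i in seq_len(spec$n_poisson)) {
    k <- k + 1
    r <- stats::runif(1, 0.5, 5)
    reg <- if (i %% 2 == 0) "HPC" else "LS"
    add_unit(generate_poisson_unit(r, dur, seed = child_seed(seed, k),
                                   unit_id = sprintf("%s_po%02d", tolower(reg), i),
                                   region = reg),
             list(type = "poisson", mean_rate = r))
  }
  sess <- session(traj$positions, trains, maze, events = traj$events,
                  session_id = sprintf("synth_seed%d", seed))
  truth <- list(seed = seed, units = truth_units, pairs = truth_pairs,
                spec = spec[setdiff(names(spec), "coupling")])
  list(session = sess, truth = truth)
}
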