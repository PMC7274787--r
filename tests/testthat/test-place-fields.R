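test_that("field detection applies the threshold, peak, and length rules", {
  cfg <- fix_cfg
  # flat map: no fields
  flat <- profile_rate_map(rep(3, nrow(fix_grid2$bins)), fix_grid2)
  expect_length(detect_fields(flat, cfg), 0)
  # planted 30 cm bump with a dominant peak: exactly one field, center
  # within 5 cm of the planted center
  tf <- truth_fields(center = 250, width_sd = 12, peak = 10)
  expect_length(tf, 1)
  expect_lt(path_distance(tf[[1]]$center_lin, 250, fix_maze), 5)
  expect_gte(tf[[1]]$length, 15)
  # low-rate units are excluded from field analysis
  lowr <- profile_rate_map(c(rep(0.0, 100), 0.04, rep(0.0, 149)), fix_grid2)
  out <- detect_fields(lowr, cfg)
  expect_length(out, 0)
  expect_equal(attr(out, "excluded"), "low_rate")
  # wrong grid
  rm1 <- profile_rate_map(rep(1, nrow(fix_grid1$bins)), fix_grid1)
  expect_error(detect_fields(rm1, cfg), "grid")
})

test_that("the 15 cm minimum length boundary is sharp", {
  # construct an unsmoothed map whose suprathreshold component has exactly
  # 7 bins (14 cm): rejected; 8 bins (16 cm): accepted
  n <- nrow(fix_grid2$bins)
  mk <- function(k) {
    v <- rep(1, n)
    sel <- 120 + seq_len(k)   # stem interior
    v[sel] <- 8
    v[sel[ceiling(k / 2)]] <- 12
    profile_rate_map(v, fix_grid2)
  }
  expect_length(detect_fields(mk(7), fix_cfg), 0)
  expect_length(detect_fields(mk(8), fix_cfg), 1)
})

test_that("field center is the argmax with a deterministic tie-break", {
  n <- nrow(fix_grid2$bins)
  v <- rep(0.5, n)
  sel <- 110 + 1:10
  v[sel] <- 6
  v[c(113, 116)] <- 10  # two equal maxima
  rm <- profile_rate_map(v, fix_grid2)
  ff <- detect_fields(rm, fix_cfg)
  expect_length(ff, 1)
  ctr <- field_center(ff[[1]], rm)
  expect_equal(ctr$bin, 113)  # lower linearized coordinate wins
  # oracle: brute-force scan of in-field bins
  expect_equal(rm$rate[ctr$bin], max(rm$rate[ff[[1]]$bins]))
})

test_that("skew is the weighted third standardized moment", {
  # frozen oracle value for the tabulated profile [1,2,4,8] at x=[1,2,3,4]
  expect_equal(mazefields:::weighted_skewness(1:4, c(1, 2, 4, 8)),
               -1.051772, tolerance = 1e-6)
  # direct moment computation as an independent check
  w <- c(1, 2, 4, 8) / 15; x <- 1:4
  mu <- sum(w * x)
  expect_equal(mazefields:::weighted_skewness(1:4, c(1, 2, 4, 8)),
               sum(w * (x - mu)^3) / sum(w * (x - mu)^2)^1.5, tolerance = 1e-12)
  # symmetric profile: zero
  expect_equal(mazefields:::weighted_skewness(1:5, c(1, 3, 9, 3, 1)), 0,
               tolerance = 1e-12)
  # mirroring flips the sign exactly
  prof <- c(0.5, 2, 7, 4, 1)
  expect_equal(mazefields:::weighted_skewness(1:5, prof),
               -mazefields:::weighted_skewness(1:5, rev(prof)),
               tolerance = 1e-12)
  # constant profile is symmetric (skew 0); degenerate profiles are NA
  expect_equal(mazefields:::weighted_skewness(1:5, rep(2, 5)), 0,
               tolerance = 1e-12)
  expect_true(is.na(mazefields:::weighted_skewness(1:5, c(0, 0, 2, 0, 0))))
  expect_true(is.na(mazefields:::weighted_skewness(1:2, c(1, 2))))
})

test_that("field_skew orients the profile along travel direction", {
  # asymmetric planted profile on the stem (mass toward the choice end)
  n <- nrow(fix_grid2$bins)
  stem <- which(fix_grid2$bins$arm == "stem")
  v <- rep(0.1, n)
  bump <- seq_along(stem)
  prof <- exp(-((bump - 25) / 5)^2 / 2) * pnorm(3 * (bump - 25) / 5)
  v[stem] <- 0.1 + 10 * prof / max(prof)
  rm <- profile_rate_map(v, fix_grid2)
  ff <- detect_fields(rm, fix_cfg)
  f <- ff[[which.max(vapply(ff, function(x) x$peak_rate, numeric(1)))]]
  sk_t <- field_skew(f, rm, fix_maze, travel = "toward")
  sk_a <- field_skew(f, rm, fix_maze, travel = "away")
  # toward-reward travel on the stem runs toward the choice end: the planted
  # late-mass profile is positively skewed along travel, and reversing the
  # travel direction flips the sign
  expect_gt(sk_t, 0)
  expect_equal(sk_t, -sk_a, tolerance = 1e-9)
})

test_that("FRAI is a bounded asymmetry index", {
  # F1 = 2 x F2 gives 1/3 (the adopted (F1-F2)/(F1+F2) form)
  tv <- list(list(entry = 0, exit = 3, spikes = c(0.9, 1.1)))
  expect_equal(field_frai(tv)$frai, 1 / 3, tolerance = 1e-9)
  # bounded in [-1, 1] on random traversals
  set.seed(81)
  rand <- lapply(1:200, function(i) {
    dur <- runif(1, 0.5, 4)
    list(entry = 0, exit = dur, spikes = sort(runif(sample(2:30, 1), 0, dur)))
  })
  vals <- field_frai(rand)$per_traversal
  expect_true(all(vals >= -1 & vals <= 1, na.rm = TRUE))
  # constant-rate traversals average near zero
  reg <- lapply(1:100, function(i)
    list(entry = 0, exit = 2, spikes = seq(0.05, 1.95, by = 0.1) +
           runif(20, -0.04, 0.04)))
  expect_lt(abs(field_frai(reg)$frai), 0.1)
  # single-spike traversals yield no value
  expect_true(is.na(field_frai(list(list(entry = 0, exit = 1, spikes = 0.5)))$frai))
})

test_that("directionality merges centers separated by under 20 cm", {
  mkf <- function(center, id = "u") structure(
    list(unit_id = id, bins = integer(0), center_bin = NA,
         center_lin = center, length = 20, peak_rate = 5,
         direction = "both"), class = "place_field")
  # 19 cm apart: bidirectional
  out <- classify_directionality(list(mkf(240)), list(mkf(259)), fix_maze)
  expect_true(all(vapply(out, function(f) f$direction, character(1)) == "both"))
  expect_length(out, 2)
  # exactly 20 cm: two unidirectional fields (strictly less than)
  out2 <- classify_directionality(list(mkf(240)), list(mkf(260)), fix_maze)
  expect_setequal(vapply(out2, function(f) f$direction, character(1)),
                  c("toward_reward", "away_from_reward"))
  # empty away list: all toward
  out3 <- classify_directionality(list(mkf(240), mkf(300)), list(), fix_maze)
  expect_true(all(vapply(out3, function(f) f$direction, character(1)) ==
                    "toward_reward"))
})

test_that("direction-split maps recover gated fields", {
  fs <- field_spec(250, 10, 12, 0.05, 0, "toward_reward")
  tr <- generate_place_cell(fs, fix_traj, fix_maze, seed = 91, unit_id = "g")
  sess <- fix_session(list(tr))
  sp <- split_by_direction(sess, sess$trains[[1]], fix_cfg)
  ft <- detect_fields(sp$toward$rm, fix_cfg)
  fa <- detect_fields(sp$away$rm, fix_cfg)
  ct <- vapply(ft, function(f) path_distance(f$center_lin, 250, fix_maze), numeric(1))
  expect_true(any(ct < 10))
  # in the away direction the cell is silent: no field near the center
  ca <- vapply(fa, function(f) path_distance(f$center_lin, 250, fix_maze), numeric(1))
  expect_false(any(ca < 10))
  # a session without reward events cannot be split
  sess2 <- session(fix_traj$positions, list(tr), fix_maze, events = NULL)
  expect_error(split_by_direction(sess2, sess2$trains[[1]], fix_cfg), "events")
})

test_that("lap stability requires 15 traversals and tracks the peak", {
  fs <- field_spec(250, 10, 15, 0.05, 0, "both")
  tr <- generate_place_cell(fs, fix_traj, fix_maze, seed = 92, unit_id = "s")
  sess <- fix_session(list(tr))
  ff <- fix_maps(tr)
  fields <- detect_fields(ff$rm, fix_cfg)
  f <- fields[[which.min(vapply(fields, function(x)
    path_distance(x$center_lin, 250, fix_maze), numeric(1)))]]
  st <- lap_stability(f, sess, tr, fix_cfg)
  expect_false(is.null(st))
  expect_gte(nrow(st), 15)
  # a stable planted cell keeps its per-lap peak near the mean center
  expect_lt(median(st$dist_from_mean), 10)
  expect_true(all(st$dist_from_mean >= 0))
  # too few traversals: excluded
  expect_null(lap_stability(f, sess, tr, fix_cfg, min_traversals = 1e6))
})

test_that("kinematic regression explains rate only when it should", {
  f <- speed_filter(fix_traj$positions, fix_kin, list(), 12, fix_maze)
  km <- kinematics_maps(f$positions, fix_grid2)
  # rate = 2 x speed map: r^2 ~ 1
  v <- ifelse(is.na(km$speed), 0, 2 * km$speed)
  rm <- profile_rate_map(v, fix_grid2)
  expect_gt(suppressWarnings(speed_accel_regression(rm, km)), 0.999)
  # rate independent of kinematics: small r^2
  set.seed(93)
  r2 <- replicate(10, {
    rnd <- profile_rate_map(rexp(nrow(fix_grid2$bins)), fix_grid2)
    speed_accel_regression(rnd, km)
  })
  expect_lt(median(r2), 0.1)
  # closed-form normal-equation oracle
  vv <- rm$visited & !is.na(km$speed)
  y <- rexp(sum(vv)); X <- cbind(1, km$speed[vv], km$accel[vv])
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2_oracle <- 1 - sum(res^2) / sum((y - mean(y))^2)
  ry <- profile_rate_map(replace(rep(0, nrow(fix_grid2$bins)), which(vv), y),
                         fix_grid2)
  expect_equal(speed_accel_regression(ry, km), r2_oracle, tolerance = 1e-9)
})
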