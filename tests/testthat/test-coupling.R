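cfg_fast <- analysis_config(n_shuffles = 10)

test_that("cross-correlogram peaks at the imposed shift", {
  h <- generate_poisson_unit(8, 300, seed = 101, unit_id = "h", region = "HPC")
  l <- h; l$unit_id <- "l"; l$region <- "LS"
  l$spike_times <- h$spike_times + 0.02
  cc <- cross_correlogram(h, l, fix_cfg, t_range = c(0, 300.2))
  expect_equal(cc$lags_ms, seq(-100, 100, by = 10))
  expect_equal(cc$lags_ms[which.max(cc$raw)], 20)
  # identical trains peak at zero lag
  cc0 <- cross_correlogram(h, h, fix_cfg, t_range = c(0, 300.2))
  expect_equal(cc0$lags_ms[which.max(cc0$raw)], 0)
  expect_error(cross_correlogram(spike_train("e", "HPC", numeric(0)), l),
               "empty spike train")
})

test_that("correlogram values match a brute-force spike-pair count", {
  set.seed(102)
  h <- spike_train("h", "HPC", sort(runif(50, 0, 20)))
  l <- spike_train("l", "LS", sort(runif(50, 0, 20)))
  tr <- c(0, 20.1)
  cc <- cross_correlogram(h, l, fix_cfg, t_range = tr)
  bin <- 0.010
  bh <- floor((h$spike_times - tr[1]) / bin)
  bl <- floor((l$spike_times - tr[1]) / bin)
  oracle <- vapply(-10:10, function(k)
    sum(outer(bl, bh, "-") == k), numeric(1)) / cc$nbins
  expect_equal(cc$raw, oracle, tolerance = 1e-12)
})

test_that("correlogram symmetry: ccg(A,B)[+k] == ccg(B,A)[-k]", {
  set.seed(103)
  h <- spike_train("h", "HPC", sort(runif(200, 0, 100)))
  l <- spike_train("l", "LS", sort(runif(150, 0, 100)))
  tr <- c(0, 100)
  ab <- cross_correlogram(h, l, fix_cfg, t_range = tr)$raw
  ba <- cross_correlogram(l, h, fix_cfg, t_range = tr)$raw
  expect_equal(ab, rev(ba), tolerance = 1e-12)
})

test_that("shuffle correction is deterministic and centers the null", {
  h <- generate_poisson_unit(6, 400, seed = 104, unit_id = "h", region = "HPC")
  l <- generate_poisson_unit(6, 400, seed = 105, unit_id = "l")
  raw <- cross_correlogram(h, l, cfg_fast, t_range = c(0, 400))
  c1 <- shuffle_correct(raw, h, l, cfg_fast, seed = 7)
  c2 <- shuffle_correct(raw, h, l, cfg_fast, seed = 7)
  expect_identical(c1$corrected, c2$corrected)
  expect_equal(c1$corrected, c1$raw - c1$shuffle_mean)
  # independent trains: corrected correlogram centered near zero
  expect_lt(abs(c1$mean_corrected), 3 * c1$shuffle_sd)
  # a planted 20 ms coupling survives the correction
  pr <- generate_coupled_pair(field_spec(250, 10, 12, 0.2, 0, "both"),
                              coupling_spec(20, 0.4, 2, 2), fix_traj,
                              fix_maze, seed = 106)
  rawp <- cross_correlogram(pr$hpc, pr$ls, cfg_fast)
  cp <- shuffle_correct(rawp, pr$hpc, pr$ls, cfg_fast, seed = 8)
  expect_equal(cp$peak_lag_ms, 20, tolerance = 10)
  expect_gt(max(cp$corrected), 0)
})

test_that("pair matching uses the 20 cm radius and the rate tie-break", {
  mkf <- function(center, id) structure(
    list(unit_id = id, bins = integer(0), center_bin = NA, center_lin = center,
         length = 20, peak_rate = 5, direction = "both"), class = "place_field")
  rates <- c(H = 2.1, A = 2.0, B = 5.0, C = 1.0)
  # exactly 20 cm: matched (inclusive); 21 cm: excluded
  p20 <- match_pairs(list(mkf(240, "H")), list(mkf(260, "A")), rates, fix_maze, fix_cfg)
  expect_equal(nrow(p20), 1)
  p21 <- match_pairs(list(mkf(240, "H")), list(mkf(261, "A")), rates, fix_maze, fix_cfg)
  expect_equal(nrow(p21), 0)
  # candidates at 10 cm (rate 5.0) and 15 cm (rate 2.0) vs HPC at 2.1 Hz:
  # the most similar rate wins even though it is farther
  pm <- match_pairs(list(mkf(250, "H")),
                    list(mkf(260, "B"), mkf(265, "A")), rates, fix_maze, fix_cfg)
  expect_equal(pm$ls_unit, "A")
  expect_equal(pm$center_distance, 15)
  # rate ties fall back to the nearer field
  rates2 <- c(H = 2.0, A = 3.0, B = 3.0)
  pmt <- match_pairs(list(mkf(250, "H")),
                     list(mkf(265, "A"), mkf(260, "B")), rates2, fix_maze, fix_cfg)
  expect_equal(pmt$ls_unit, "B")
})

test_that("pair summaries aggregate exactly and split by arm", {
  mkc <- function(m, p) structure(list(mean_corrected = m, peak_lag_ms = p),
                                  class = "cross_correlogram")
  pairs <- data.frame(hpc_unit = c("a", "b", "c"), ls_unit = c("x", "y", "z"),
                      hpc_center = c(10, 20, 400), ls_center = c(12, 22, 402),
                      center_distance = 2, rate_difference = 0.1,
                      arm_group = c("forced", "forced", "choice"))
  ccgs <- list(mkc(0.1, 20), mkc(0.3, 10), mkc(0.5, 20))
  s <- summarize_pairs(pairs, ccgs)
  expect_equal(s$groups$mean_corr[s$groups$arm_group == "forced"], 0.2)
  expect_equal(s$groups$mean_corr[s$groups$arm_group == "choice"], 0.5)
  expect_equal(s$groups$mean_peak_lag_ms[s$groups$arm_group == "forced"], 15)
})

test_that("session thirds partition time half-open and drop sparse pairs", {
  h <- generate_poisson_unit(5, 300, seed = 107, unit_id = "h", region = "HPC")
  l <- generate_poisson_unit(5, 300, seed = 108, unit_id = "l")
  pos <- position_series(seq(0, 300, by = 1), seq(0, 300), rep(0, 301), 1)
  sess <- suppressMessages(session(pos, list(h, l), build_maze(100, 400)))
  pairs <- data.frame(hpc_unit = "h", ls_unit = "l", hpc_center = 250,
                      ls_center = 250, center_distance = 0,
                      rate_difference = 0, arm_group = "middle")
  trains <- list(h = sess$trains[[1]], l = sess$trains[[2]])
  th <- session_thirds(pairs, sess, trains, cfg_fast, seed = 5)
  expect_equal(sort(unique(th$third)), 1:3)
  # the thirds cover each spike exactly once
  cuts <- sess$t0 + sess$duration * 0:3 / 3
  counts <- vapply(1:3, function(i)
    sum(h$spike_times >= cuts[i] & h$spike_times < cuts[i + 1]), numeric(1))
  expect_equal(sum(counts), sum(h$spike_times < cuts[4]))
})
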