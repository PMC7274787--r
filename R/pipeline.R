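# Full-session orchestration and the statistical tests used for group
# comparisons. Group t-tests use the pooled-variance (Student) form so the
# degrees of freedom follow the n1 + n2 - 2 convention.

#' Group comparison tests
#'
#' Pooled-variance two-sample t (two-tailed), one-sample t, paired t,
#' two-sample Kolmogorov-Smirnov, or Pearson chi-square on a count table.
#' For `"chisq"`, pass the count matrix/table as `a`.
#'
#' @param a first group (numeric), or a count table for `"chisq"`
#' @param b second group (numeric; NULL for one-sample)
#' @param test one of `"t"`, `"one_sample_t"`, `"paired_t"`, `"ks"`,
#'   `"chisq"`
#' @param mu null value for the one-sample t
#' @return list: `statistic`, `df` (NA for KS), `p`
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("t", "one_sample_t", "paired_t", "ks", "chisq"),
                           mu = 0) {
  test <- match.arg(test)
  res <- switch(test,
    t = {
      if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group for a t-test")
      stats::t.test(a, b, var.equal = TRUE)
    },
    one_sample_t = stats::t.test(a, mu = mu),
    paired_t = stats::t.test(a, b, paired = TRUE),
    ks = stats::ks.test(a, b),
    chisq = stats::chisq.test(a)
  )
  list(statistic = unname(res$statistic),
       df = if (!is.null(res$parameter)) unname(res$parameter) else NA_real_,
       p = res$p.value)
}

#' Run the full analysis pipeline on a session
#'
#' simulate/load -> kinematics -> speed filter -> information -> fields (by
#' direction) -> directionality -> locations and reward-distance histograms
#' -> pair matching and shuffle-corrected correlograms -> group statistics.
#' Every stage logs its exclusion counts via `message()`.
#'
#' @param sess a `session` (e.g. from [generate_session()] or
#'   [read_session()])
#' @param config an `analysis_config`
#' @param seed seed for the correlogram shuffles (defaults to the config's)
#' @return a `report_bundle`: `config`, `info` (per-unit information table),
#'   `fields` (fields table), `locations`, `arm_tally` (per region),
#'   `reward_histogram` (per region), `pairs`, `pair_summary`, `thirds`,
#'   `stats` (test table), `r2_speed_accel`
#' @export
run_full_analysis <- function(sess, config = analysis_config(), seed = NULL) {
  seed <- seed %||% config$rng_seed
  kin <- compute_acceleration(compute_speed(sess$positions, config$speed_smooth_sd))
  filt <- speed_filter(sess$positions, kin, sess$trains, config$speed_threshold,
                       sess$maze)
  attr(filt, "kin") <- kin
  message("speed filter: ", nrow(filt$positions), " fast samples, ",
          round(filt$total_time, 1), " s retained")
  info <- classify_units(sess, config)
  message("information: ", sum(info$passes_cutoff), "/", nrow(info),
          " units pass the ", config$bits_cutoff, " bits/spike cutoff (",
          sum(!is.na(info$excluded_reason)), " excluded)")

  grid2 <- track_grid(sess$maze, config$field_bin)
  unit_rates <- stats::setNames(info$mean_rate, info$unit_id)
  trains_by_id <- stats::setNames(sess$trains,
                                  vapply(sess$trains, function(t) t$unit_id, character(1)))
  all_fields <- list(); field_rows <- list()
  kin_map <- kinematics_maps(filt$positions, grid2)
  r2 <- c()
  for (i in seq_along(sess$trains)) {
    tr <- sess$trains[[i]]
    if (!isTRUE(info$passes_cutoff[info$unit_id == tr$unit_id])) next
    sp <- split_by_direction(sess, tr, config, filt = filt)
    ft <- if (!is.null(sp$toward)) detect_fields(sp$toward$rm, config, "toward_reward") else list()
    fa <- if (!is.null(sp$away)) detect_fields(sp$away$rm, config, "away_from_reward") else list()
    fields <- classify_directionality(ft, fa, sess$maze, config$match_radius)
    for (f in fields) {
      f$region <- tr$region
      travel <- if (f$direction == "away_from_reward") "away" else "toward"
      rm_dir <- if (travel == "toward" && !is.null(sp$toward)) sp$toward$rm else sp$away$rm
      f$skew <- field_skew(f, rm_dir, sess$maze, travel = travel)
      trav <- field_traversals(f, sess, tr, config, filt = filt)
      f$n_traversals <- length(trav)
      f$frai <- if (length(trav)) field_frai(trav)$frai else NA_real_
      all_fields[[length(all_fields) + 1]] <- f
      field_rows[[length(field_rows) + 1]] <- data.frame(
        unit_id = f$unit_id, region = tr$region, direction = f$direction,
        center_cm = f$center_lin, length_cm = f$length,
        peak_rate = f$peak_rate, skew = f$skew, frai = f$frai,
        n_traversals = f$n_traversals, stringsAsFactors = FALSE)
    }
    # kinematic control on the whole-session field map of this unit
    occ2 <- occupancy_map(filt$positions, grid2)
    ftr <- filt$trains[[i]]
    rm2 <- rate_map(ftr, filt$positions, occ2, config$map_smooth_sd)
    r2 <- c(r2, stats::setNames(speed_accel_regression(rm2, kin_map), tr$unit_id))
  }
  fields_tab <- if (length(field_rows)) do.call(rbind, field_rows) else
    data.frame(unit_id = character(0), region = character(0),
               direction = character(0), center_cm = numeric(0),
               length_cm = numeric(0), peak_rate = numeric(0),
               skew = numeric(0), frai = numeric(0), n_traversals = integer(0))
  message("fields: ", nrow(fields_tab), " detected across ",
          length(unique(fields_tab$unit_id)), " units")

  region_of <- function(f) f$region
  locs <- assign_field_locations(all_fields, sess$maze)
  if (nrow(locs)) locs$region <- vapply(all_fields, region_of, character(1))
  tallies <- hists <- list()
  for (reg in c("HPC", "LS")) {
    fl <- all_fields[vapply(all_fields, region_of, character(1)) == reg]
    if (!length(fl)) next
    tallies[[reg]] <- arm_tally(assign_field_locations(fl, sess$maze))
    hists[[reg]] <- field_probability_by_distance(fl, sess$maze)
  }

  regions <- vapply(all_fields, region_of, character(1))
  hpc_fields <- all_fields[regions == "HPC"]
  ls_fields <- all_fields[regions == "LS"]
  pairs <- match_pairs(hpc_fields, ls_fields, unit_rates, sess$maze, config)
  message("pairs: ", nrow(pairs), " HPC-LS field pairs matched")
  ccgs <- list(); summary_pairs <- NULL; thirds <- NULL
  if (nrow(pairs) > 0) {
    ccgs <- lapply(seq_len(nrow(pairs)), function(i) {
      h <- trains_by_id[[pairs$hpc_unit[i]]]; l <- trains_by_id[[pairs$ls_unit[i]]]
      raw <- cross_correlogram(h, l, config, t_range = c(sess$t0, sess$t1))
      shuffle_correct(raw, h, l, config, seed = child_seed(seed, i))
    })
    summary_pairs <- summarize_pairs(pairs, ccgs)
    thirds <- session_thirds(pairs, sess, trains_by_id, config, seed = seed)
  }

  stats_rows <- list()
  add_stat <- function(name, input, res) {
    stats_rows[[length(stats_rows) + 1]] <<- data.frame(
      test = name, input = input, statistic = res$statistic, df = res$df,
      p = res$p, stringsAsFactors = FALSE)
  }
  bh <- info$bits_per_spike[info$region == "HPC" & is.na(info$excluded_reason)]
  bl <- info$bits_per_spike[info$region == "LS" & is.na(info$excluded_reason)]
  if (length(bh) >= 2 && length(bl) >= 2)
    add_stat("pooled_t_bits_per_spike_HPC_vs_LS", "info", compare_groups(bh, bl, "t"))
  if (nrow(fields_tab) >= 4) {
    lh <- fields_tab$length_cm[fields_tab$region == "HPC"]
    ll <- fields_tab$length_cm[fields_tab$region == "LS"]
    if (length(lh) >= 2 && length(ll) >= 2)
      add_stat("pooled_t_field_length_HPC_vs_LS", "fields", compare_groups(lh, ll, "t"))
  }
  if (!is.null(summary_pairs) && !is.null(summary_pairs$tests)) {
    for (i in seq_len(nrow(summary_pairs$tests))) {
      tt <- summary_pairs$tests[i, ]
      add_stat(paste0("pooled_t_mean_corr_", tt$group_a, "_vs_", tt$group_b),
               "pairs", list(statistic = tt$statistic, df = tt$df, p = tt$p))
    }
  }
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL

  structure(list(config = config, info = info, fields = fields_tab,
                 field_objects = all_fields, locations = locs,
                 arm_tally = tallies, reward_histogram = hists,
                 pairs = pairs, ccgs = ccgs, pair_summary = summary_pairs,
                 thirds = thirds, stats = stats_tab,
                 r2_speed_accel = r2, seed = seed),
            class = "report_bundle")
}

#' Write report tables to CSV
#'
#' Deterministically ordered CSV tables (info, fields, locations, pairs,
#' per-pair correlograms, group summaries, statistics) plus a JSON config
#' snapshot.
#'
#' @param report a `report_bundle`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    key <- intersect(c("unit_id", "field_id", "third", "hpc_unit"), names(df))
    if (length(key)) df <- df[do.call(order, df[, key, drop = FALSE]), , drop = FALSE]
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(report$info, "info.csv")
  wr(report$fields, "fields.csv")
  wr(report$locations, "locations.csv")
  wr(report$pairs, "pairs.csv")
  if (!is.null(report$pair_summary)) {
    utils::write.csv(report$pair_summary$groups, file.path(dir, "pair_groups.csv"),
                     row.names = FALSE)
  }
  if (length(report$ccgs)) {
    ccg_tab <- do.call(rbind, lapply(report$ccgs, function(c)
      data.frame(hpc_unit = c$hpc_unit, ls_unit = c$ls_unit,
                 lag_ms = c$lags_ms, raw = c$raw, corrected = c$corrected)))
    utils::write.csv(ccg_tab, file.path(dir, "ccgs.csv"), row.names = FALSE)
  }
  wr(report$thirds, "thirds.csv")
  if (!is.null(report$stats))
    utils::write.csv(report$stats, file.path(dir, "stats.csv"), row.names = FALSE)
  for (reg in names(report$reward_histogram))
    utils::write.csv(report$reward_histogram[[reg]],
                     file.path(dir, paste0("reward_histogram_", reg, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(unclass(report$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
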