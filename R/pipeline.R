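# End-to-end orchestration: condition simulation/analysis, normalization to
# a reference condition, labeling correction, statistics, and CSV/JSON
# reports that are reproducible from (config, seed) alone.

#' Welch two-sample test
#'
#' Two-sided unequal-variance t test on per-replicate values (per
#' microtubule or per imaging field), the convention for condition
#' comparisons in single-molecule motility work. Degenerate inputs (fewer
#' than two values or zero variance in both groups) are an error rather
#' than a silent NA.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("each group needs at least 2 values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
    stopf("both groups have zero variance; test is degenerate")
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}

#' @noRd
default_analysis_params <- function() {
  list(min_run_length_nm = 500, min_duration_s = 2, max_pause_s = 3,
       assoc_radius_nm = 320, step_tol_nm = 80, censored_min_disp_nm = 160,
       end_exclusion_nm = 1000, min_mt_length_um = 10, coloc_radius_nm = 300,
       threshold_k = 5, max_disp_nm = 640, max_gap_frames = 2)
}

# straight microtubules at random angles, fully inside the field with a
# margin; lengths uniform in [lmin, lmax] um
#' @noRd
random_paths <- function(n, cfg, lmin_um = 15, lmax_um = 30,
                         margin_nm = 1000) {
  W <- cfg$field_size_nm[1] - 2 * margin_nm
  H <- cfg$field_size_nm[2] - 2 * margin_nm
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      L <- stats::runif(1, lmin_um, lmax_um) * 1000
      th <- stats::runif(1, 0, 2 * pi)
      x0 <- stats::runif(1, 0, W) + margin_nm
      y0 <- stats::runif(1, 0, H) + margin_nm
      x1 <- x0 + L * cos(th); y1 <- y0 + L * sin(th)
      if (x1 >= margin_nm && x1 <= W + margin_nm &&
          y1 >= margin_nm && y1 <= H + margin_nm) break
    }
    out[[i]] <- mt_path(rbind(c(x0, y0), c(x1, y1)), id = i)
  }
  out
}

#' Assign tracks to their best-matching microtubule
#'
#' Each track goes to the path minimizing the median perpendicular distance
#' of its points, provided that median is within `assoc_radius_nm`.
#' Movers briefly crossing another filament are thereby counted only on
#' their own filament, not double-counted on the crossed one.
#'
#' @param tracks data.frame with `track_id`, `x_nm`, `y_nm`.
#' @param paths list of [mt_path()].
#' @param assoc_radius_nm association cutoff on the median distance, nm.
#' @return data.frame `track_id`, `path_index`, `path_id`, `median_dist_nm`
#'   (unassignable tracks are omitted).
#' @export
assign_tracks_to_paths <- function(tracks, paths, assoc_radius_nm = 320) {
  ids <- unique(tracks$track_id)
  if (length(ids) == 0L)
    return(data.frame(track_id = integer(), path_index = integer(),
                      path_id = character(), median_dist_nm = numeric()))
  med <- matrix(Inf, length(ids), length(paths))
  for (pi in seq_along(paths)) {
    pr <- project_onto_path(paths[[pi]], cbind(tracks$x_nm, tracks$y_nm))
    med[, pi] <- vapply(split(pr$dist_nm, match(tracks$track_id, ids)),
                        stats::median, numeric(1))[as.character(seq_along(ids))]
  }
  best <- max.col(-med, ties.method = "first")
  bd <- med[cbind(seq_along(ids), best)]
  keep <- bd <= assoc_radius_nm
  data.frame(track_id = ids[keep], path_index = best[keep],
             path_id = vapply(paths[best[keep]], function(p) format(p$id),
                              character(1)),
             median_dist_nm = bd[keep])
}

#' Analyze one motility condition from tracks
#'
#' Runs run detection over all microtubules and computes the
#' per-microtubule frequency statistic and velocity distribution; the
#' shared downstream half of both the simulated and the real-data motility
#' pipeline.
#'
#' @param tracks data.frame (`track_id`, `frame`, `x_nm`, `y_nm`).
#' @param paths list of [mt_path()] (already length-filtered or not; the
#'   `min_mt_length_um` cut in `params` is applied here).
#' @param cfg a [sim_config()].
#' @param params analysis parameter list; missing entries take the package
#'   defaults (see the methods vignette).
#' @return list with `runs`, `frequency` (a `frequency_result`),
#'   `velocities`, `paths_used`.
#' @export
analyze_motility <- function(tracks, paths, cfg, params = list()) {
  p <- utils::modifyList(default_analysis_params(), params)
  paths <- filter_microtubules(paths, p$min_mt_length_um)
  if (length(paths) == 0L) stopf("no microtubule passes the length cut")
  assignment <- assign_tracks_to_paths(tracks, paths, p$assoc_radius_nm)
  runs <- list()
  for (pi in seq_along(paths)) {
    path <- paths[[pi]]
    ids <- assignment$track_id[assignment$path_index == pi]
    if (length(ids) == 0L) next
    r <- detect_runs(tracks[tracks$track_id %in% ids, , drop = FALSE],
                     path, cfg$frame_interval_s,
                     acquisition_frames = cfg$n_frames,
                     min_run_length_nm = p$min_run_length_nm,
                     min_duration_s = p$min_duration_s,
                     max_pause_s = p$max_pause_s,
                     assoc_radius_nm = p$assoc_radius_nm,
                     step_tol_nm = p$step_tol_nm,
                     censored_min_disp_nm = p$censored_min_disp_nm,
                     end_exclusion_nm = p$end_exclusion_nm)
    if (nrow(r) > 0L) runs[[length(runs) + 1L]] <- r
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    detect_runs(NULL, paths[[1]], cfg$frame_interval_s)
  # a landing is countable only if it is sampled in >= 2 frames, which
  # (with mid-exposure sampling) happens exactly when it lands before
  # T - 1.5 dt: normalize by the observable window, the temporal analogue
  # of the end-exclusion border correction
  t_obs <- cfg$duration_s - 1.5 * cfg$frame_interval_s
  freq <- run_frequency(runs, paths, t_obs,
                        end_exclusion_nm = p$end_exclusion_nm)
  list(runs = runs, frequency = freq,
       velocities = run_velocity(runs[!runs$censored, , drop = FALSE]),
       paths_used = paths)
}

#' Run the full pipeline from a config
#'
#' Executes simulate -> (optionally detect/track) -> run detection ->
#' frequency/velocity -> normalization per condition, plus optional
#' binding/dwell and mass-photometry sections, and writes `frequency.csv`,
#' `runs.csv`, `summary.csv` (and `dwell_fit.json` / `mixture.json` when
#' those sections are configured) into the output directory. Deterministic
#' given the config seed: re-running reproduces every file byte for byte.
#'
#' @param config a config list (see the bundled
#'   `inst/extdata/pipeline_demo.yaml`) or the path to a YAML file.
#' @param out_dir output directory (created); defaults to `config$output`.
#' @param quiet suppress progress messages?
#' @return (invisibly) list of per-condition results plus `summary`
#'   data.frame.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$output %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed %||% 1L)
  conditions <- config$conditions %||% list()
  if (length(conditions) == 0L) {
    say("no conditions declared; nothing to do")
    return(invisible(list(summary = data.frame())))
  }
  imaging <- config$imaging %||% list()
  cfg_base <- do.call(sim_config, imaging)
  params <- config$analysis %||% list()
  p_full <- utils::modifyList(default_analysis_params(), params)

  results <- list()
  ref_label <- NULL
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    label <- cond$label %||% sprintf("condition_%d", ci)
    if (isTRUE(cond$reference)) ref_label <- label
    say("condition '%s': simulating (f_true = %g)", label, cond$f_true)
    cfg <- cfg_base
    cfg$rng_seed <- seed + ci
    n_mt <- as.integer(cond$n_microtubules %||% 20L)
    set_seed_if(cfg$rng_seed)
    paths <- random_paths(n_mt, cfg,
                          lmin_um = cond$mt_length_min_um %||% 15,
                          lmax_um = cond$mt_length_max_um %||% 30)
    sim <- simulate_motility_movie(
      cfg, paths, f_true = cond$f_true,
      velocity_mean_nms = cond$velocity_mean_nms %||% 500,
      velocity_sd_nms = cond$velocity_sd_nms %||% 100,
      run_length_mean_nm = cond$run_length_mean_nm %||% 8000,
      min_run_length_nm = p_full$min_run_length_nm,
      min_duration_s = p_full$min_duration_s,
      render = "none")
    tracks <- truth_tracks(sim$truth, cfg)
    res <- analyze_motility(tracks, paths, cfg, params)
    res$label <- label
    res$f_true <- cond$f_true
    res$seed <- cfg$rng_seed
    results[[label]] <- res
  }
  if (is.null(ref_label)) ref_label <- results[[1]]$label
  ref <- results[[ref_label]]$frequency

  rows <- list()
  freq_rows <- list()
  run_rows <- list()
  for (res in results) {
    norm <- normalize_frequency(res$frequency, ref)
    tt <- if (res$label != ref_label &&
              stats::sd(res$frequency$per_mt$frequency) > 0 &&
              stats::sd(ref$per_mt$frequency) > 0)
      two_sample_test(res$frequency$per_mt$frequency,
                      ref$per_mt$frequency)$p_value else NA_real_
    rows[[res$label]] <- data.frame(
      condition = res$label, f_true = res$f_true, seed = res$seed,
      n_mt = res$frequency$n_mt, n_runs = sum(res$frequency$per_mt$n_runs),
      freq_mean = res$frequency$mean, freq_sd = res$frequency$sd,
      fold_vs_reference = norm$fold_mean,
      velocity_mean_nms = if (length(res$velocities)) mean(res$velocities)
                          else NA_real_,
      velocity_sd_nms = if (length(res$velocities) > 1)
        stats::sd(res$velocities) else NA_real_,
      p_vs_reference = tt)
    freq_rows[[res$label]] <- data.frame(condition = res$label,
                                         res$frequency$per_mt)
    if (nrow(res$runs))
      run_rows[[res$label]] <- data.frame(condition = res$label, res$runs)
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  write_report_csv <- function(df, file)
    utils::write.csv(format_report(df), file.path(out_dir, file),
                     row.names = FALSE, quote = FALSE)
  write_report_csv(summary_df, "summary.csv")
  write_report_csv(do.call(rbind, freq_rows), "frequency.csv")
  if (length(run_rows))
    write_report_csv(do.call(rbind, run_rows), "runs.csv")

  out <- list(conditions = results, summary = summary_df,
              reference = ref_label)

  if (!is.null(config$dwell)) {
    dw <- config$dwell
    cfg <- cfg_base
    cfg$rng_seed <- seed + 1000L
    say("dwell section: tau = %g s", dw$tau_s)
    bsim <- simulate_binding_movie(cfg, n_baits = dw$n_baits %||% 50,
                                   tau_s = dw$tau_s,
                                   gap_mean_s = dw$gap_mean_s %||% 60,
                                   render = "none")
    ev <- bsim$truth$events
    events <- data.frame(duration_s = ev$t_off - ev$t_on,
                         censored = ev$censored)
    events <- events[events$duration_s >= 2 * cfg$frame_interval_s, ,
                     drop = FALSE]
    fit <- fit_exponential(events, method = dw$method %||% "mle")
    jsonlite::write_json(
      list(tau_s = round(fit$tau_s, 4), se_s = round(fit$se_s, 4),
           n = fit$n, n_censored = fit$n_censored, method = fit$method),
      file.path(out_dir, "dwell_fit.json"), auto_unbox = TRUE)
    out$dwell <- fit
  }

  if (!is.null(config$massphot)) {
    mp <- config$massphot
    say("mass photometry section: K = %d", length(mp$components))
    truth_mix <- do.call(rbind, lapply(mp$components, as.data.frame))
    x <- sample_masses(truth_mix, n = mp$n_samples %||% 5000,
                       seed = seed + 2000L)
    fit <- fit_mixture(x, K = nrow(truth_mix),
                       shape_fixed = mp$shape_fixed,
                       seed = seed + 2001L)
    jsonlite::write_json(
      list(components = lapply(seq_len(nrow(fit$components)), function(k)
        list(mean_kda = round(fit$components$mean_kda[k], 2),
             sd_kda = round(fit$components$sd_kda[k], 2),
             percent = population_percentages(fit)[k])),
        loglik = round(fit$loglik, 2), n = fit$n),
      file.path(out_dir, "mixture.json"), auto_unbox = TRUE)
    out$massphot <- fit
  }

  # provenance header: the report is self-describing
  jsonlite::write_json(
    list(seed = seed, reference = ref_label,
         analysis_params = p_full,
         imaging = imaging,
         package_version = as.character(utils::packageVersion("ddrquant"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  say("report written to %s", out_dir)
  invisible(out)
}

# fixed-notation rounding so reports are byte-stable across platforms
#' @noRd
format_report <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- trimws(formatC(signif(df[[j]], 8),
                                                      format = "g",
                                                      digits = 8))
  }
  df
}
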