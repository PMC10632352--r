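# Synthetic TIRF experiment generator: ground-truth-annotated movies for
# motility (movers on microtubule tracks) and binding (static bait, blinking
# prey) assays, plus mass-photometry sample draws.

#' Render one fluorescence frame
#'
#' Each emitter contributes an integrated isotropic 2D Gaussian PSF: the
#' photon count expected in a pixel is the emitter's total photons times the
#' product of error-function differences over the pixel edges (pixel (1,1)
#' spans `[0, pixel] x [0, pixel]` nm; its center sits at half a pixel).
#' Noise, when enabled, is Poisson shot noise on (signal + background),
#' EM-register excess noise (Gamma with mean `em_gain` per electron, which
#' doubles the variance for large gain) when `em_gain > 1`, then additive
#' Gaussian read noise. Pixel values are clamped at 0.
#'
#' @param emitters data.frame with columns `x_nm`, `y_nm`, `photons`
#'   (expected photons emitted into the frame). May have zero rows.
#' @param cfg a [sim_config()].
#' @param noise logical; `FALSE` returns the noiseless expectation (no
#'   background noise, but the constant background level is still added).
#' @return numeric matrix `[ny, nx]` of pixel values.
#' @export
render_frame <- function(emitters, cfg, noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  nx <- cfg$n_pixels[1]; ny <- cfg$n_pixels[2]
  px <- cfg$pixel_size_nm
  img <- matrix(cfg$background_photons, nrow = ny, ncol = nx)
  if (!is.null(emitters) && nrow(emitters) > 0L) {
    halfw <- ceiling(5 * cfg$psf_sigma_nm / px)
    s <- cfg$psf_sigma_nm
    for (i in seq_len(nrow(emitters))) {
      if (emitters$photons[i] <= 0) next
      cx <- emitters$x_nm[i] / px   # position in pixel units (edge-origin)
      cy <- emitters$y_nm[i] / px
      jx <- max(1L, floor(cx) - halfw + 1L):min(nx, ceiling(cx) + halfw)
      jy <- max(1L, floor(cy) - halfw + 1L):min(ny, ceiling(cy) + halfw)
      if (length(jx) == 0L || length(jy) == 0L) next
      fx <- diff(stats::pnorm(c(jx[1] - 1L, jx) * px, emitters$x_nm[i], s))
      fy <- diff(stats::pnorm(c(jy[1] - 1L, jy) * px, emitters$y_nm[i], s))
      img[jy, jx] <- img[jy, jx] + emitters$photons[i] * (fy %o% fx)
    }
  }
  if (noise) {
    counts <- stats::rpois(length(img), img)
    if (cfg$em_gain > 1) {
      out <- numeric(length(counts))
      pos <- counts > 0L
      out[pos] <- stats::rgamma(sum(pos), shape = counts[pos],
                                scale = cfg$em_gain)
      counts <- out
    }
    if (cfg$read_noise_sd > 0)
      counts <- counts + stats::rnorm(length(counts), sd = cfg$read_noise_sd)
    img <- matrix(pmax(counts, 0), nrow = ny, ncol = nx)
  } else if (cfg$em_gain > 1) {
    img <- img * cfg$em_gain
  }
  img
}

# draw one truncated normal > 0 by rejection (velocities)
#' @noRd
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate a motility movie with ground truth
#'
#' Landings on each microtubule are Poisson with mean `f_true * L * T`
#' (runs per micrometer of filament per second times length times duration),
#' uniform in time and arc position. Each landing starts a processive run
#' toward increasing arc length with a velocity drawn from a positive
#' truncated normal. Run lengths are exponential *conditioned on
#' processivity*: a run, by the same definition the detector uses, travels at
#' least `max(min_run_length_nm, v * min_duration_s)`, so lengths are that
#' threshold plus an exponential excess (the memoryless conditional law).
#' Runs detach at the filament end or are cut by the end of the acquisition;
#' both truncations are flagged in the truth table.
#'
#' @param cfg a [sim_config()]; `cfg$rng_seed` (if set) fixes all draws.
#' @param paths list of [mt_path()] objects; every polyline must lie inside
#'   the field.
#' @param f_true landing rate of processive runs, runs um^-1 s^-1 (>= 0).
#' @param velocity_mean_nms,velocity_sd_nms run velocity distribution, nm/s.
#' @param run_length_mean_nm mean exponential excess run length, nm.
#' @param min_run_length_nm,min_duration_s the processivity definition the
#'   truth conditions on (keep in sync with [detect_runs()]).
#' @param label a [labeling_model()] for the mover; complexes with zero dyes
#'   are present in the truth but dark in the movie.
#' @param render `"full"` renders every frame; `"none"` skips rendering and
#'   returns `movie = NULL` (track-level simulation for statistics at scale).
#' @return list with `movie` (array `[ny, nx, n_frames]` or NULL), `truth`
#'   (class `motility_truth`: `runs` data.frame, `paths`, `f_true`, and the
#'   velocity/length parameters), and `cfg`.
#' @examples
#' cfg <- sim_config(field_size_um = c(10, 10), n_frames = 50, rng_seed = 1)
#' mt <- mt_path(rbind(c(500, 5000), c(9500, 5000)))
#' sim <- simulate_motility_movie(cfg, list(mt), f_true = 2e-3,
#'                                render = "none")
#' nrow(sim$truth$runs)
#' @export
simulate_motility_movie <- function(cfg, paths, f_true,
                                    velocity_mean_nms = 500,
                                    velocity_sd_nms = 100,
                                    run_length_mean_nm = 8000,
                                    min_run_length_nm = 500,
                                    min_duration_s = 2,
                                    label = labeling_model(1, 1),
                                    render = c("full", "none")) {
  stopifnot(inherits(cfg, "sim_config"))
  render <- match.arg(render)
  if (inherits(paths, "mt_path")) paths <- list(paths)
  if (length(paths) < 1L) stopf("need at least one microtubule path")
  assert_scalar_num(f_true, "f_true", nonneg = TRUE)
  assert_scalar_num(velocity_mean_nms, "velocity_mean_nms", positive = TRUE)
  assert_scalar_num(velocity_sd_nms, "velocity_sd_nms", nonneg = TRUE)
  assert_scalar_num(run_length_mean_nm, "run_length_mean_nm", positive = TRUE)
  for (p in paths) {
    if (any(p$vertices[, 1] < 0 | p$vertices[, 1] > cfg$field_size_nm[1] |
            p$vertices[, 2] < 0 | p$vertices[, 2] > cfg$field_size_nm[2]))
      stopf("path %s extends outside the %g x %g um field",
            format(p$id), cfg$field_size_um[1], cfg$field_size_um[2])
  }
  set_seed_if(cfg$rng_seed)
  TT <- cfg$duration_s

  runs <- list()
  for (p in paths) {
    L_um <- path_length_um(p)
    n_land <- stats::rpois(1, f_true * L_um * TT)
    if (n_land == 0L) next
    t_on <- stats::runif(n_land, 0, TT)
    arc_on <- stats::runif(n_land, 0, p$length_nm)
    v <- rtnorm_pos(n_land, velocity_mean_nms, velocity_sd_nms)
    # processivity conditioning: at least the detection minima plus one
    # frame-interval of travel, so a processive run is always resolvable
    # at the sampling rate (memoryless exponential excess beyond that)
    lmin <- pmax(min_run_length_nm, v * min_duration_s) +
      v * cfg$frame_interval_s
    len <- lmin + stats::rexp(n_land, rate = 1 / run_length_mean_nm)
    dur_detach <- len / v
    dur_end <- (p$length_nm - arc_on) / v
    dur_movie <- TT - t_on
    dur <- pmin(dur_detach, dur_end, dur_movie)
    runs[[length(runs) + 1L]] <- data.frame(
      mt_id = rep(p$id, n_land), t_on = t_on, t_off = t_on + dur,
      arc_on = arc_on, arc_off = arc_on + v * dur, v_nms = v,
      censored_end = dur_end < pmin(dur_detach, dur_movie),
      censored_time = dur_movie < pmin(dur_detach, dur_end))
  }
  runs <- if (length(runs)) do.call(rbind, runs) else data.frame(
    mt_id = integer(), t_on = numeric(), t_off = numeric(),
    arc_on = numeric(), arc_off = numeric(), v_nms = numeric(),
    censored_end = logical(), censored_time = logical())
  if (nrow(runs) > 0L) {
    runs <- runs[order(runs$t_on), , drop = FALSE]
    runs$run_id <- seq_len(nrow(runs))
    runs$n_dyes <- draw_dye_count(label, nrow(runs))
    rownames(runs) <- NULL
  } else {
    runs$run_id <- integer()
    runs$n_dyes <- integer()
  }

  truth <- structure(list(runs = runs, paths = paths, f_true = f_true,
                          velocity_mean_nms = velocity_mean_nms,
                          velocity_sd_nms = velocity_sd_nms,
                          run_length_mean_nm = run_length_mean_nm),
                     class = "motility_truth")
  movie <- if (render == "full") render_motility(truth, cfg) else NULL
  list(movie = movie, truth = truth, cfg = cfg)
}

# frame mid-exposure times, 1-based frames
#' @noRd
frame_times <- function(cfg) (seq_len(cfg$n_frames) - 0.5) * cfg$frame_interval_s

#' Ground-truth tracks from a motility truth table
#'
#' Per-frame true emitter positions of every run (mid-exposure sampling),
#' the noiseless counterpart of what [link_tracks()] reconstructs.
#'
#' @param truth a `motility_truth` (from [simulate_motility_movie()]).
#' @param cfg the matching [sim_config()].
#' @param visible_only drop runs that carry zero dyes?
#' @return data.frame: `track_id` (= run id), `mt_id`, `frame`, `t_s`,
#'   `arc_nm`, `x_nm`, `y_nm`.
#' @export
truth_tracks <- function(truth, cfg, visible_only = FALSE) {
  stopifnot(inherits(truth, "motility_truth"))
  tf <- frame_times(cfg)
  runs <- truth$runs
  if (visible_only) runs <- runs[runs$n_dyes > 0L, , drop = FALSE]
  paths_by_id <- stats::setNames(truth$paths,
                                 vapply(truth$paths, function(p)
                                   format(p$id), character(1)))
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    fr <- which(tf >= r$t_on & tf <= r$t_off)
    if (length(fr) == 0L) next
    arc <- r$arc_on + r$v_nms * (tf[fr] - r$t_on)
    xy <- path_point(paths_by_id[[format(r$mt_id)]], arc)
    out[[i]] <- data.frame(track_id = r$run_id, mt_id = r$mt_id, frame = fr,
                           t_s = tf[fr], arc_nm = arc,
                           x_nm = xy[, 1], y_nm = xy[, 2])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(track_id = integer(), mt_id = integer(),
                      frame = integer(), t_s = numeric(), arc_nm = numeric(),
                      x_nm = numeric(), y_nm = numeric()))
  do.call(rbind, out)
}

#' @noRd
render_motility <- function(truth, cfg) {
  tr <- truth_tracks(truth, cfg, visible_only = TRUE)
  dyes <- stats::setNames(truth$runs$n_dyes, truth$runs$run_id)
  # per-dye bleach times (exponential), if enabled
  bleach <- is.finite(cfg$bleach_tau_s)
  if (bleach) {
    bl <- lapply(truth$runs$n_dyes, function(k)
      if (k > 0) stats::rexp(k, 1 / cfg$bleach_tau_s) else numeric())
    names(bl) <- truth$runs$run_id
    t_on <- stats::setNames(truth$runs$t_on, truth$runs$run_id)
  }
  per_frame_photons <- cfg$photon_rate_per_dye * cfg$frame_interval_s
  movie <- array(0, c(cfg$n_pixels[2], cfg$n_pixels[1], cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    sub <- tr[tr$frame == f, , drop = FALSE]
    if (nrow(sub) > 0L) {
      n_active <- if (bleach) {
        vapply(seq_len(nrow(sub)), function(i) {
          id <- as.character(sub$track_id[i])
          sum(bl[[id]] > sub$t_s[i] - t_on[id])
        }, numeric(1))
      } else dyes[as.character(sub$track_id)]
      em <- data.frame(x_nm = sub$x_nm, y_nm = sub$y_nm,
                       photons = n_active * per_frame_photons)
    } else em <- NULL
    movie[, , f] <- render_frame(em, cfg, noise = TRUE)
  }
  movie
}

#' Simulate a two-color binding movie with ground truth
#'
#' A static bait channel (surface-immobilized complexes, one emitter per
#' bait, present in every frame) and a prey channel in which each bait hosts
#' a renewal sequence of binding episodes: exponential gaps (mean
#' `gap_mean_s`) alternating with exponential dwells (mean `tau_s`). Episodes
#' still bound at the end of the acquisition are truncated there and flagged
#' censored. Baits are placed uniformly at random (or supplied); a warning is
#' given when the expected nearest-neighbor spacing drops below 4 PSF sigma.
#'
#' @param cfg a [sim_config()].
#' @param n_baits number of baits (ignored when `bait_xy` is given).
#' @param tau_s mean dwell (residence) time, seconds (> 0).
#' @param gap_mean_s mean unbound gap between episodes on one bait, seconds.
#' @param bait_xy optional matrix of bait positions (nm).
#' @param prey_label a [labeling_model()] applied per episode (dark episodes
#'   stay in the truth).
#' @param render `"full"` or `"none"` as in [simulate_motility_movie()].
#' @return list with `movies` (list `bait`, `prey` of arrays, or NULL),
#'   `truth` (class `binding_truth`: `baits` data.frame, `events` data.frame
#'   with `bait_id`, `t_on`, `t_off`, `censored`, `n_dyes`), and `cfg`.
#' @export
simulate_binding_movie <- function(cfg, n_baits = 50, tau_s = 21,
                                   gap_mean_s = 60, bait_xy = NULL,
                                   prey_label = labeling_model(1, 1),
                                   render = c("full", "none")) {
  stopifnot(inherits(cfg, "sim_config"))
  render <- match.arg(render)
  assert_scalar_num(tau_s, "tau_s", positive = TRUE)
  assert_scalar_num(gap_mean_s, "gap_mean_s", positive = TRUE)
  set_seed_if(cfg$rng_seed)
  if (is.null(bait_xy)) {
    n_baits <- as.integer(n_baits)
    if (n_baits < 0L) stopf("'n_baits' must be >= 0")
    bait_xy <- cbind(stats::runif(n_baits, 0, cfg$field_size_nm[1]),
                     stats::runif(n_baits, 0, cfg$field_size_nm[2]))
  } else {
    bait_xy <- matrix(as.numeric(bait_xy), ncol = 2L)
    n_baits <- nrow(bait_xy)
  }
  if (n_baits > 1L) {
    # Poisson-process expected nearest-neighbor distance: 1/(2 sqrt(rho))
    rho <- n_baits / prod(cfg$field_size_nm)
    if (1 / (2 * sqrt(rho)) < 4 * cfg$psf_sigma_nm)
      warnf("bait density is high: expected spacing %.0f nm < 4 PSF sigma",
            1 / (2 * sqrt(rho)))
  }
  baits <- data.frame(bait_id = seq_len(n_baits),
                      x_nm = bait_xy[, 1], y_nm = bait_xy[, 2])
  TT <- cfg$duration_s
  ev <- list()
  for (b in seq_len(n_baits)) {
    t <- stats::rexp(1, 1 / gap_mean_s)
    while (t < TT) {
      dwell <- stats::rexp(1, 1 / tau_s)
      censored <- t + dwell >= TT
      ev[[length(ev) + 1L]] <- data.frame(
        bait_id = b, t_on = t, t_off = min(t + dwell, TT),
        censored = censored)
      t <- t + dwell + stats::rexp(1, 1 / gap_mean_s)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    bait_id = integer(), t_on = numeric(), t_off = numeric(),
    censored = logical())
  events$n_dyes <- if (nrow(events)) draw_dye_count(prey_label, nrow(events))
                   else integer()
  rownames(events) <- NULL
  truth <- structure(list(baits = baits, events = events, tau_s = tau_s,
                          gap_mean_s = gap_mean_s),
                     class = "binding_truth")
  movies <- NULL
  if (render == "full") {
    per_frame_photons <- cfg$photon_rate_per_dye * cfg$frame_interval_s
    tf <- frame_times(cfg)
    ny <- cfg$n_pixels[2]; nx <- cfg$n_pixels[1]
    bait_movie <- array(0, c(ny, nx, cfg$n_frames))
    prey_movie <- array(0, c(ny, nx, cfg$n_frames))
    bait_em <- data.frame(x_nm = baits$x_nm, y_nm = baits$y_nm,
                          photons = rep(per_frame_photons, n_baits))
    for (f in seq_len(cfg$n_frames)) {
      bait_movie[, , f] <- render_frame(bait_em, cfg, noise = TRUE)
      on <- events[events$t_on <= tf[f] & events$t_off >= tf[f] &
                     events$n_dyes > 0L, , drop = FALSE]
      em <- if (nrow(on)) data.frame(
        x_nm = baits$x_nm[on$bait_id], y_nm = baits$y_nm[on$bait_id],
        photons = on$n_dyes * per_frame_photons) else NULL
      prey_movie[, , f] <- render_frame(em, cfg, noise = TRUE)
    }
    movies <- list(bait = bait_movie, prey = prey_movie)
  }
  list(movies = movies, truth = truth, cfg = cfg)
}

#' Draw mass-photometry samples from a skew-normal mixture
#'
#' Component membership is multinomial in the weights; values are drawn from
#' each component's skew-normal law. Used to feed the mixture-fitting stage
#' with a recoverable truth.
#'
#' @param mixture a data.frame with columns `location`, `scale`, `shape`,
#'   `weight` (weights > 0, summing to 1), or an [sn_mixture] fit object.
#' @param n number of samples.
#' @param seed optional seed.
#' @return numeric vector of masses (kDa), with the component assignment in
#'   attribute `"component"`.
#' @export
sample_masses <- function(mixture, n, seed = NULL) {
  if (inherits(mixture, "sn_mixture")) mixture <- mixture$components
  if (!is.data.frame(mixture) || nrow(mixture) == 0L)
    stopf("'mixture' must be a non-empty data.frame of components")
  req <- c("location", "scale", "shape", "weight")
  if (!all(req %in% names(mixture)))
    stopf("'mixture' needs columns %s", paste(req, collapse = ", "))
  if (any(mixture$weight < 0) || abs(sum(mixture$weight) - 1) > 1e-8)
    stopf("component weights must be >= 0 and sum to 1")
  set_seed_if(seed)
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  x <- rskewnorm(n, mixture$location[comp], mixture$scale[comp],
                 mixture$shape[comp])
  attr(x, "component") <- comp
  x
}

#' Write a simulated experiment to disk
#'
#' Movies go to one multi-page TIFF per channel, truth tables to CSV
#' (`runs.csv` / `events.csv` + `baits.csv`), paths to `paths.csv`, and the
#' resolved configuration to `config.yaml`.
#'
#' @param sim result of [simulate_motility_movie()] or
#'   [simulate_binding_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$cfg
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), c("field_size_nm"))],
                   file.path(dir, "config.yaml"))
  if (inherits(sim$truth, "motility_truth")) {
    utils::write.csv(sim$truth$runs, file.path(dir, "runs.csv"),
                     row.names = FALSE)
    write_paths_csv(sim$truth$paths, file.path(dir, "paths.csv"))
    if (!is.null(sim$movie))
      write_tiff_stack(file.path(dir, "movie_ch1.tif"), sim$movie)
  } else if (inherits(sim$truth, "binding_truth")) {
    utils::write.csv(sim$truth$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth$baits, file.path(dir, "baits.csv"),
                     row.names = FALSE)
    if (!is.null(sim$movies)) {
      write_tiff_stack(file.path(dir, "movie_bait.tif"), sim$movies$bait)
      write_tiff_stack(file.path(dir, "movie_prey.tif"), sim$movies$prey)
    }
  }
  invisible(dir)
}
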