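# Kymograph construction along microtubule paths, processive-run detection,
# and per-microtubule run-frequency / velocity statistics.

#' Build a kymograph along a microtubule path
#'
#' For every frame, intensity is sampled by bilinear interpolation at
#' arc-length steps of `bin_nm` along the polyline and averaged over
#' `width_px` samples placed perpendicular to the path (one pixel apart).
#' Rows are time (increasing downward), columns arc length — the
#' conventional kymograph orientation.
#'
#' @param movie array `[ny, nx, n_frames]`.
#' @param path an [mt_path()]; must lie inside the movie field.
#' @param cfg a [sim_config()] (pixel size, frame interval).
#' @param width_px odd number of perpendicular averaging samples.
#' @param bin_nm arc-length bin (defaults to the pixel size).
#' @return object of class `kymograph`: list with `intensity` (matrix
#'   `n_frames x n_bins`), `bin_nm`, `frame_interval_s`, `path_id`,
#'   `width_px`.
#' @export
build_kymograph <- function(movie, path, cfg, width_px = 3, bin_nm = NULL) {
  stopifnot(inherits(path, "mt_path"), inherits(cfg, "sim_config"))
  if (is.matrix(movie)) movie <- array(movie, c(dim(movie), 1L))
  bin_nm <- bin_nm %||% cfg$pixel_size_nm
  if (width_px %% 2 != 1) stopf("'width_px' must be odd")
  px <- cfg$pixel_size_nm
  arcs <- seq(bin_nm / 2, path$length_nm, by = bin_nm)
  n_bins <- length(arcs)
  ctr <- path_point(path, arcs)
  nrm <- path_frame(path, arcs)$normal
  offsets <- (seq_len(width_px) - (width_px + 1) / 2) * px
  # sample grid: n_bins x width_px points, in pixel units
  sx <- (outer(ctr[, 1], rep(1, width_px)) + outer(nrm[, 1], offsets)) / px
  sy <- (outer(ctr[, 2], rep(1, width_px)) + outer(nrm[, 2], offsets)) / px
  ny <- dim(movie)[1]; nx <- dim(movie)[2]
  # pixel centers at (i - 0.5); convert to fractional index space
  fx <- sx + 0.5; fy <- sy + 0.5
  if (any(fx < 1 | fx > nx | fy < 1 | fy > ny))
    stopf("path %s (with averaging width) exits the movie field",
          format(path$id))
  x0 <- pmin(floor(fx), nx - 1L); y0 <- pmin(floor(fy), ny - 1L)
  wx <- fx - x0; wy <- fy - y0
  n_frames <- dim(movie)[3]
  out <- matrix(0, n_frames, n_bins)
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0) + 1L)
  i10 <- cbind(as.vector(y0) + 1L, as.vector(x0))
  i11 <- cbind(as.vector(y0) + 1L, as.vector(x0) + 1L)
  w00 <- as.vector((1 - wx) * (1 - wy)); w01 <- as.vector(wx * (1 - wy))
  w10 <- as.vector((1 - wx) * wy); w11 <- as.vector(wx * wy)
  for (f in seq_len(n_frames)) {
    fr <- movie[, , f]
    vals <- w00 * fr[i00] + w01 * fr[i01] + w10 * fr[i10] + w11 * fr[i11]
    out[f, ] <- rowMeans(matrix(vals, n_bins, width_px))
  }
  structure(list(intensity = out, bin_nm = bin_nm,
                 frame_interval_s = cfg$frame_interval_s,
                 path_id = path$id, width_px = width_px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph of path %s: %d frames x %d bins (%g nm, %g s)\n",
              format(x$path_id), nrow(x$intensity), ncol(x$intensity),
              x$bin_nm, x$frame_interval_s))
  invisible(x)
}

#' Detect processive runs from tracks along a path
#'
#' Tracks are projected onto the path (points farther than
#' `assoc_radius_nm` from the polyline are discarded) and scanned for
#' maximal intervals of sustained unidirectional arc-length displacement. A
#' segment ends when the motion reverses by more than `step_tol_nm` or
#' pauses longer than `max_pause_s`. Accepted runs must satisfy both
#' processivity minima (`min_run_length_nm` and `min_duration_s`); segments
#' truncated by the filament end or by the end of the acquisition are
#' exempt from the minima (they are censored, not short) provided they
#' displace at least `censored_min_disp_nm`. Static and diffusive binders
#' fail the thresholds and are excluded.
#'
#' With `end_exclusion_nm > 0`, runs that *start* within that distance of
#' the filament end they move toward are dropped; pairing this with the
#' matching `effective_length` correction in [run_frequency()] removes the
#' edge bias of runs landing too close to the end to be classified.
#'
#' @param tracks data.frame with `track_id`, `frame`, `x_nm`, `y_nm`
#'   (e.g. from [link_tracks()] or [truth_tracks()]).
#' @param path an [mt_path()].
#' @param frame_interval_s seconds per frame.
#' @param acquisition_frames total frames in the movie (for end-censoring);
#'   defaults to the largest frame present.
#' @param min_run_length_nm,min_duration_s processivity thresholds.
#' @param max_pause_s tolerated pause inside a run, seconds.
#' @param assoc_radius_nm max perpendicular distance from the path.
#' @param step_tol_nm motion tolerance: displacements smaller than this are
#'   a pause, opposite displacements larger than this end the run.
#' @param censored_min_disp_nm displacement floor for censored segments.
#' @param end_exclusion_nm landing-zone border correction (see above).
#' @return data.frame of runs: `path_id`, `track_id`, `t_start`, `t_end`,
#'   `arc_start`, `arc_end`, `displacement_nm`, `velocity_nms`, `direction`,
#'   `censored`.
#' @export
detect_runs <- function(tracks, path, frame_interval_s,
                        acquisition_frames = NULL,
                        min_run_length_nm = 500, min_duration_s = 2,
                        max_pause_s = 3, assoc_radius_nm = 320,
                        step_tol_nm = 80, censored_min_disp_nm = 160,
                        end_exclusion_nm = 0) {
  stopifnot(inherits(path, "mt_path"))
  empty <- data.frame(path_id = character(), track_id = integer(),
                      t_start = numeric(), t_end = numeric(),
                      arc_start = numeric(), arc_end = numeric(),
                      displacement_nm = numeric(), velocity_nms = numeric(),
                      direction = integer(), censored = logical())
  if (is.null(tracks) || nrow(tracks) == 0L) return(empty)
  acquisition_frames <- acquisition_frames %||% max(tracks$frame)
  proj <- project_onto_path(path, cbind(tracks$x_nm, tracks$y_nm))
  on_path <- proj$dist_nm <= assoc_radius_nm
  tr <- tracks[on_path, , drop = FALSE]
  tr$arc <- proj$arc_nm[on_path]
  if (nrow(tr) == 0L) return(empty)

  out <- list()
  for (id in unique(tr$track_id)) {
    g <- tr[tr$track_id == id, , drop = FALSE]
    g <- g[order(g$frame), , drop = FALSE]
    segs <- split_monotone_segments(g$arc, g$frame, frame_interval_s,
                                    step_tol_nm, max_pause_s)
    for (sg in segs) {
      i0 <- sg[1]; i1 <- sg[2]
      if (i1 <= i0) next
      a0 <- g$arc[i0]; a1 <- g$arc[i1]
      span <- g$frame[i1] - g$frame[i0]
      if (span < 1L) next
      dir <- sign(a1 - a0)
      seg_v <- abs(a1 - a0) / (span * frame_interval_s)
      # half-frame correction: the mover entered before the first sampled
      # frame and left after the last, so the frame-quantized duration and
      # displacement each gain one frame-step (unbiased under uniform
      # landing phase)
      dur <- (span + 1L) * frame_interval_s
      disp <- abs(a1 - a0) + seg_v * frame_interval_s
      # a mover can be sampled up to one frame-step short of the filament
      # end before detaching there, so the end tolerance is one step
      end_tol <- seg_v * frame_interval_s + step_tol_nm
      reaches_end <- (dir > 0 && path$length_nm - a1 <= end_tol) ||
        (dir < 0 && a1 <= end_tol)
      # truncation by the filament end or by the end of the acquisition
      # exempts a segment from the processivity minima (it is censored,
      # not short); being in progress at the movie start only flags it
      # censored (a landing before the observation window must still meet
      # the full criteria to be counted)
      exempt <- reaches_end || g$frame[i1] >= acquisition_frames
      censored <- exempt || g$frame[i0] <= 1L
      ok <- (disp >= min_run_length_nm && dur >= min_duration_s) ||
        (exempt && disp >= censored_min_disp_nm)
      if (!ok) next
      arc_start <- a0 - dir * seg_v * frame_interval_s / 2
      arc_end <- a1 + dir * seg_v * frame_interval_s / 2
      if (end_exclusion_nm > 0) {
        # arc_start back-extrapolates half a frame to the expected landing
        # position, keeping the border-correction cut unbiased
        dist_to_dest <- if (dir > 0) path$length_nm - arc_start
                        else arc_start
        if (dist_to_dest < end_exclusion_nm) next
      }
      out[[length(out) + 1L]] <- data.frame(
        path_id = format(path$id), track_id = id,
        t_start = (g$frame[i0] - 1L) * frame_interval_s,
        t_end = g$frame[i1] * frame_interval_s,
        arc_start = arc_start, arc_end = arc_end, displacement_nm = disp,
        velocity_nms = seg_v, direction = as.integer(dir),
        censored = censored)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal same-direction intervals in an arc series; returns list of
# c(start_index, end_index) pairs
#' @noRd
split_monotone_segments <- function(arc, frame, dt, step_tol, max_pause) {
  n <- length(arc)
  segs <- list()
  i <- 1L
  while (i < n) {
    # find the first significant step to set the direction
    j <- i + 1L
    while (j <= n && abs(arc[j] - arc[i]) <= step_tol) j <- j + 1L
    if (j > n) break
    dir <- sign(arc[j] - arc[i])
    start <- i
    extreme <- arc[j]; ext_idx <- j
    k <- j
    while (k < n) {
      nxt <- arc[k + 1L]
      adv <- dir * (nxt - extreme)
      if (adv > 0) {
        extreme <- nxt; ext_idx <- k + 1L
      } else if (adv < -step_tol) {
        break  # reversal
      } else if ((frame[k + 1L] - frame[ext_idx]) * dt > max_pause) {
        break  # stalled too long
      }
      k <- k + 1L
    }
    segs[[length(segs) + 1L]] <- c(start, ext_idx)
    i <- if (ext_idx > start) ext_idx else i + 1L
  }
  segs
}

#' Run velocity
#'
#' Speed of a detected run: absolute arc displacement over elapsed time
#' (nm/s); the sign of travel is in the run's `direction` column.
#'
#' @param runs data.frame from [detect_runs()] (or any frame with
#'   `arc_start`, `arc_end`, `t_start`, `t_end`).
#' @return numeric vector of velocities, nm/s.
#' @export
run_velocity <- function(runs) {
  if (nrow(runs) == 0L) return(numeric())
  dt <- runs$t_end - runs$t_start
  if (any(dt <= 0)) stopf("runs must have t_end > t_start")
  abs(runs$arc_end - runs$arc_start) / dt
}

#' Per-microtubule run frequency
#'
#' The field's standard landing-rate statistic: for each microtubule the
#' number of processive runs divided by filament length (um) and acquisition
#' duration (s); summarized as mean +/- sd over microtubules (each filament
#' is one replicate, no pooling).
#'
#' @param runs data.frame from [detect_runs()] (with `path_id`).
#' @param paths list of [mt_path()] objects defining the denominator set;
#'   microtubules with zero runs count as zeros.
#' @param duration_s acquisition duration, seconds (> 0).
#' @param end_exclusion_nm when runs were detected with a landing-zone
#'   border correction, the same value here shortens each filament's
#'   effective length accordingly.
#' @return object of class `frequency_result`: list with `per_mt`
#'   (data.frame `path_id`, `length_um`, `n_runs`, `frequency`), `mean`,
#'   `sd`, `n_mt`.
#' @export
run_frequency <- function(runs, paths, duration_s, end_exclusion_nm = 0) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (inherits(paths, "mt_path")) paths <- list(paths)
  if (length(paths) == 0L) stopf("'paths' must contain at least one microtubule")
  ids <- vapply(paths, function(p) format(p$id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate path ids")
  L_eff <- vapply(paths, path_length_um, numeric(1)) - end_exclusion_nm / 1000
  if (any(L_eff <= 0)) stopf("effective microtubule length must be > 0")
  n_runs <- if (nrow(runs) > 0L) {
    if (!all(runs$path_id %in% ids))
      stopf("runs reference paths absent from 'paths'")
    tab <- table(factor(runs$path_id, levels = ids))
    as.integer(tab)
  } else rep(0L, length(ids))
  freq <- n_runs / (L_eff * duration_s)
  per_mt <- data.frame(path_id = ids,
                       length_um = vapply(paths, path_length_um, numeric(1)),
                       n_runs = n_runs, frequency = freq)
  structure(list(per_mt = per_mt, mean = mean(freq),
                 sd = if (length(freq) > 1L) stats::sd(freq) else 0,
                 n_mt = length(ids)),
            class = "frequency_result")
}

#' @export
print.frequency_result <- function(x, ...) {
  cat(sprintf(
    "run frequency: %.3g +/- %.3g runs um^-1 s^-1 (mean +/- sd, n = %d MTs)\n",
    x$mean, x$sd, x$n_mt))
  invisible(x)
}

#' Normalize run frequencies to a reference condition
#'
#' Divides every per-microtubule frequency by the reference condition's mean
#' frequency, so the reference condition normalizes to 1 by construction.
#'
#' @param result a `frequency_result` for the condition of interest.
#' @param reference_result the reference `frequency_result` (its mean must
#'   be > 0).
#' @return list with `fold_values` (per-MT fold changes), `fold_mean`,
#'   `fold_sd`.
#' @export
normalize_frequency <- function(result, reference_result) {
  stopifnot(inherits(result, "frequency_result"),
            inherits(reference_result, "frequency_result"))
  if (!is.finite(reference_result$mean) || reference_result$mean <= 0)
    stopf("reference mean frequency must be > 0 to normalize")
  folds <- result$per_mt$frequency / reference_result$mean
  list(fold_values = folds, fold_mean = mean(folds),
       fold_sd = if (length(folds) > 1L) stats::sd(folds) else 0)
}
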