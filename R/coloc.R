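# Two-color colocalization: static bait-prey matching, comigration of
# moving complexes, and release-latency extraction.

# one-to-one greedy matching, closest pairs first; xy in nm.
# returns data.frame(i, j, dist) of matched (bait row, prey row) pairs.
#' @noRd
greedy_match <- function(bait_xy, prey_xy, r_max_nm) {
  nb <- nrow(bait_xy); np <- nrow(prey_xy)
  if (nb == 0L || np == 0L)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  d <- sqrt(outer(bait_xy[, 1], prey_xy[, 1], "-")^2 +
              outer(bait_xy[, 2], prey_xy[, 2], "-")^2)
  ord <- order(d)
  used_b <- logical(nb); used_p <- logical(np)
  out <- list()
  for (k in ord) {
    if (d[k] > r_max_nm) break
    i <- (k - 1L) %% nb + 1L
    j <- (k - 1L) %/% nb + 1L
    if (used_b[i] || used_p[j]) next
    used_b[i] <- TRUE; used_p[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(i = i, j = j, dist = d[k])
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  do.call(rbind, out)
}

#' Match bait and prey spots within a distance cutoff
#'
#' One-to-one matching of diffraction-limited spot positions from two
#' registered channels: candidate pairs within `r_max_nm` are accepted
#' closest-first, each spot used at most once. The colocalized fraction is
#' matched bait / total bait (the paper-style statistic: LD655 spots within
#' 300 nm of an Alexa488 spot over all Alexa488 spots, with the
#' surface-immobilized channel as bait).
#'
#' @param bait_spots,prey_spots data.frames with `x_nm`, `y_nm` (or 2-column
#'   matrices).
#' @param r_max_nm matching radius, nm (default 300, the conventional
#'   peak-to-peak cutoff).
#' @return object of class `coloc_result`: list with `matches` (data.frame
#'   `bait`, `prey`, `dist_nm`), `fraction`, `n_bait`, `n_prey`,
#'   `r_max_nm`. An empty bait set is an error (undefined fraction).
#' @export
match_spots <- function(bait_spots, prey_spots, r_max_nm = 300) {
  assert_scalar_num(r_max_nm, "r_max_nm", positive = TRUE)
  as_xy <- function(s) {
    if (is.data.frame(s)) as.matrix(s[, c("x_nm", "y_nm")])
    else matrix(as.numeric(s), ncol = 2L)
  }
  b <- as_xy(bait_spots); p <- as_xy(prey_spots)
  if (nrow(b) == 0L) stopf("empty bait set: colocalized fraction undefined")
  m <- greedy_match(b, p, r_max_nm)
  structure(list(
    matches = data.frame(bait = m$i, prey = m$j, dist_nm = m$dist),
    fraction = nrow(m) / nrow(b),
    n_bait = nrow(b), n_prey = nrow(p), r_max_nm = r_max_nm),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization: %d / %d bait matched within %g nm (%.1f%%)\n",
              nrow(x$matches), x$n_bait, x$r_max_nm, 100 * x$fraction))
  invisible(x)
}

#' Expected chance colocalization for random prey placement
#'
#' If prey spots form a spatial Poisson process of density `rho` per um^2,
#' the probability that a bait has at least one prey within radius `r` is
#' `1 - exp(-rho * pi * r^2)` — the baseline a measured colocalized
#' fraction should be compared against.
#'
#' @param prey_density_per_um2 prey density, spots per um^2 (>= 0).
#' @param r_max_nm matching radius, nm.
#' @return expected random-colocalization fraction.
#' @examples
#' chance_colocalization(0.1, 300)  # ~0.028
#' @export
chance_colocalization <- function(prey_density_per_um2, r_max_nm = 300) {
  if (any(prey_density_per_um2 < 0)) stopf("density must be >= 0")
  assert_scalar_num(r_max_nm, "r_max_nm", positive = TRUE)
  r_um <- r_max_nm / 1000
  1 - exp(-prey_density_per_um2 * pi * r_um^2)
}

#' Fraction of runs comigrating with a second channel
#'
#' A processive run in channel A comigrates with channel B if some single
#' B track stays within `r_max_nm` of the run's moving position for at
#' least `min_overlap_fraction` of the frames the run spans.
#'
#' @param runs data.frame from [detect_runs()] (channel A).
#' @param tracks_a channel-A tracks the runs were detected from
#'   (`track_id`, `frame`, `x_nm`, `y_nm`) — supplies the per-frame moving
#'   positions.
#' @param tracks_b channel-B tracks, same movie and registration.
#' @param r_max_nm colocalization radius, nm.
#' @param min_overlap_fraction required fraction of run frames with a
#'   B-companion (default 0.8).
#' @return list with `fraction`, `comigrating` (logical per run), `n_runs`.
#' @export
comigration_fraction <- function(runs, tracks_a, tracks_b, r_max_nm = 300,
                                 min_overlap_fraction = 0.8) {
  if (nrow(runs) == 0L)
    return(list(fraction = NA_real_, comigrating = logical(), n_runs = 0L))
  comig <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    a <- tracks_a[tracks_a$track_id == runs$track_id[k], , drop = FALSE]
    if (nrow(a) == 0L) next
    a <- a[order(a$frame), , drop = FALSE]
    fr_lo <- min(a$frame); fr_hi <- max(a$frame)
    n_fr <- nrow(a)
    if (n_fr == 0L) next
    b <- tracks_b[tracks_b$frame >= fr_lo & tracks_b$frame <= fr_hi, ,
                  drop = FALSE]
    if (nrow(b) == 0L) next
    best <- 0
    for (bid in unique(b$track_id)) {
      bt <- b[b$track_id == bid, , drop = FALSE]
      mi <- match(a$frame, bt$frame)
      ok <- !is.na(mi)
      if (!any(ok)) next
      d <- sqrt((a$x_nm[ok] - bt$x_nm[mi[ok]])^2 +
                  (a$y_nm[ok] - bt$y_nm[mi[ok]])^2)
      best <- max(best, sum(d <= r_max_nm) / n_fr)
    }
    comig[k] <- best >= min_overlap_fraction
  }
  list(fraction = mean(comig), comigrating = comig, n_runs = nrow(runs))
}

#' Presence series from a track intensity trace
#'
#' Classifies each frame as "present" when the intensity exceeds
#' `background + k * noise_sd`, with hysteresis: present/absent states must
#' persist for `min_frames` consecutive frames to switch (single-frame
#' blinks and dropouts are bridged).
#'
#' @param intensity numeric vector, one value per frame.
#' @param background background level.
#' @param noise_sd noise standard deviation.
#' @param k threshold in noise SDs (default 3).
#' @param min_frames hysteresis length in frames (default 2).
#' @return logical vector of per-frame presence.
#' @export
presence_from_intensity <- function(intensity, background, noise_sd, k = 3,
                                    min_frames = 2L) {
  raw <- intensity > background + k * noise_sd
  n <- length(raw)
  if (n == 0L || min_frames <= 1L) return(raw)
  out <- raw
  r <- rle(out)
  # flip state stretches shorter than min_frames (except at the edges,
  # where the true state is unknown)
  if (length(r$lengths) > 2L) {
    pos <- cumsum(r$lengths)
    for (s in 2:(length(r$lengths) - 1L)) {
      if (r$lengths[s] < min_frames) {
        idx <- (pos[s - 1L] + 1L):pos[s]
        out[idx] <- !r$values[s]
      }
    }
  }
  out
}

#' Release latency of a regulator from an activating complex
#'
#' Measures the delay between the disappearance of a colocalized prey
#' signal (e.g. Nde1 leaving a dynein complex) and the onset of processive
#' motility of the bait. Disappearance is the last present frame of the
#' prey presence series before (or at) onset; the event is labelled
#' `"comigrated"` when the prey is still present at motility onset, and
#' `"released"` otherwise. If the bait never moves (`onset_s = NA`) no
#' event is produced (censored complex, reported separately).
#'
#' @param prey_presence logical per-frame presence of the prey at the bait
#'   position (see [presence_from_intensity()]).
#' @param onset_s motility onset time, seconds (e.g. `t_start` of the first
#'   run from [detect_runs()]), or `NA` if the bait never moved.
#' @param frame_interval_s seconds per frame.
#' @return one-row data.frame `t_disappear_s`, `t_onset_s`, `latency_s`,
#'   `outcome` ("released" / "comigrated" / "censored"; latency is `NA`
#'   unless released).
#' @export
release_latency <- function(prey_presence, onset_s, frame_interval_s) {
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (is.na(onset_s))
    return(data.frame(t_disappear_s = NA_real_, t_onset_s = NA_real_,
                      latency_s = NA_real_, outcome = "censored"))
  t <- (seq_along(prey_presence) - 0.5) * frame_interval_s
  onset_frame <- which(t >= onset_s)[1]
  if (is.na(onset_frame)) onset_frame <- length(prey_presence) + 1L
  present_at_onset <- onset_frame <= length(prey_presence) &&
    prey_presence[onset_frame]
  if (present_at_onset)
    return(data.frame(t_disappear_s = NA_real_, t_onset_s = onset_s,
                      latency_s = NA_real_, outcome = "comigrated"))
  last_present <- max(which(prey_presence[seq_len(min(onset_frame - 1L,
                                                      length(prey_presence)))]),
                      -Inf)
  if (!is.finite(last_present))
    return(data.frame(t_disappear_s = NA_real_, t_onset_s = onset_s,
                      latency_s = NA_real_, outcome = "censored"))
  t_dis <- t[last_present] + frame_interval_s / 2  # end of last present frame
  data.frame(t_disappear_s = t_dis, t_onset_s = onset_s,
             latency_s = max(onset_s - t_dis, 0), outcome = "released")
}
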