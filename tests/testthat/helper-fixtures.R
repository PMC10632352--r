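# shared fixtures and independent oracles, built in code at test time

# small, fast imaging config
tiny_cfg <- function(field_um = 8, n_frames = 20, seed = 1, ...) {
  sim_config(field_size_um = c(field_um, field_um), frame_interval_s = 0.6,
             n_frames = n_frames, rng_seed = seed, ...)
}

# horizontal microtubule across a field, nm coordinates
straight_path <- function(length_um = 20, y_um = NULL, x0_um = 1, id = 1L,
                          cfg = NULL) {
  y <- if (!is.null(y_um)) y_um * 1000 else
    if (!is.null(cfg)) cfg$field_size_nm[2] / 2 else 4000
  mt_path(rbind(c(x0_um * 1000, y), c(x0_um * 1000 + length_um * 1000, y)),
          id = id)
}

# synthetic tracks for a constant-velocity mover along a path
mover_tracks <- function(path, v_nms, t_on, t_off, cfg, track_id = 1L,
                         arc_on = 0) {
  tf <- (seq_len(cfg$n_frames) - 0.5) * cfg$frame_interval_s
  fr <- which(tf >= t_on & tf <= t_off)
  arc <- pmin(arc_on + v_nms * (tf[fr] - t_on), path$length_nm)
  xy <- path_point(path, arc)
  data.frame(track_id = track_id, frame = fr, x_nm = xy[, 1], y_nm = xy[, 2])
}

# exhaustive maximum matching oracle: over all conflict-free subsets of the
# <= r_max edge set, maximize pair count, then minimize total distance.
# Independent of the greedy implementation under test.
brute_force_match <- function(bait_xy, prey_xy, r_max) {
  nb <- nrow(bait_xy); np <- nrow(prey_xy)
  d <- sqrt(outer(bait_xy[, 1], prey_xy[, 1], "-")^2 +
              outer(bait_xy[, 2], prey_xy[, 2], "-")^2)
  edges <- which(d <= r_max, arr.ind = TRUE)
  best <- list(count = 0L, cost = 0)
  recurse <- function(k, used_b, used_p, count, cost) {
    remaining <- nrow(edges) - k + 1L
    if (count + remaining < best$count) return()
    if (k > nrow(edges)) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return()
    }
    i <- edges[k, 1]; j <- edges[k, 2]
    if (!used_b[i] && !used_p[j]) {
      used_b[i] <- TRUE; used_p[j] <- TRUE
      recurse(k + 1L, used_b, used_p, count + 1L, cost + d[edges[k, 1],
                                                           edges[k, 2]])
      used_b[i] <- FALSE; used_p[j] <- FALSE
    }
    recurse(k + 1L, used_b, used_p, count, cost)
  }
  if (nrow(edges) > 0L)
    recurse(1L, logical(nb), logical(np), 0L, 0)
  best
}

# numerical censored-exponential likelihood maximizer (oracle for the
# closed-form MLE)
numeric_censored_mle <- function(durations, censored) {
  nll <- function(tau) {
    ll <- sum(stats::dexp(durations[!censored], 1 / tau, log = TRUE)) +
      sum(stats::pexp(durations[censored], 1 / tau, lower.tail = FALSE,
                      log.p = TRUE))
    -ll
  }
  stats::optimize(nll, c(1e-3, 1e4))$minimum
}
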