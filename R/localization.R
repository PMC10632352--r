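# Spot localization: difference-of-Gaussians candidate detection, sub-pixel
# integrated-Gaussian least-squares fitting, and greedy nearest-neighbor
# track linking with gap closing.

# separable Gaussian convolution with reflected edges
#' @noRd
gauss_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad <- function(m, n) rbind(m[n:1, , drop = FALSE], m,
                              m[nrow(m):(nrow(m) - n + 1L), , drop = FALSE])
  conv_rows <- function(m) {
    p <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Detect candidate spots in one frame
#'
#' Difference-of-Gaussians bandpass matched to the PSF scale, thresholded at
#' `threshold_k` times the robust noise level (1.4826 x MAD of the response),
#' followed by 8-neighborhood local-maximum selection. Candidates closer
#' than `min_separation_px` keep only the brighter one.
#'
#' @param image numeric matrix (one frame).
#' @param threshold_k detection threshold in robust noise SDs (> 0).
#' @param min_separation_px minimum candidate spacing, pixels.
#' @param psf_sigma_px PSF sigma in pixels (sets the DoG scales
#'   `sigma` and `1.6 sigma`).
#' @return data.frame `row`, `col` (1-based pixel indices), `response`;
#'   zero rows when nothing exceeds threshold (a constant image is not an
#'   error).
#' @export
detect_spots <- function(image, threshold_k = 5, min_separation_px = 3,
                         psf_sigma_px = 170 / 160) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("'image' must be a numeric matrix")
  assert_scalar_num(threshold_k, "threshold_k", positive = TRUE)
  dog <- gauss_blur(image, psf_sigma_px) - gauss_blur(image, 1.6 * psf_sigma_px)
  noise <- robust_sd(as.numeric(dog))
  if (noise == 0) noise <- stats::sd(as.numeric(dog))
  if (is.na(noise) || noise == 0)
    return(data.frame(row = integer(), col = integer(), response = numeric()))
  thr <- threshold_k * noise
  ny <- nrow(dog); nx <- ncol(dog)
  # strict local maxima over the 8-neighborhood (interior pixels only)
  inner <- dog[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- dog[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    is_max <- is_max & (inner >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), response = numeric()))
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     response = dog[cbind(idx[, 1] + 1L, idx[, 2] + 1L)])
  cand <- cand[order(-cand$response, cand$row, cand$col), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$row - cand$row[i])^2 + (prev$col - cand$col[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# integrated-Gaussian model over a pixel window; pixels indexed 1-based,
# positions in pixel units with the (r, c) pixel spanning [c-1, c] x [r-1, r]
#' @noRd
int_gauss_patch <- function(rows, cols, x0, y0, sigma) {
  fx <- diff(stats::pnorm(c(cols[1] - 1L, cols), x0, sigma))
  fy <- diff(stats::pnorm(c(rows[1] - 1L, rows), y0, sigma))
  fy %o% fx
}

#' Fit a sub-pixel Gaussian to one candidate spot
#'
#' Nonlinear least squares of `offset + N * IntegratedGaussian(x0, y0,
#' sigma)` on a square window around the candidate pixel, the PSF model
#' used by single-molecule localization tools. Positions are returned in
#' nanometers (pixel (1,1) spans `[0, px] x [0, px]`).
#'
#' @param image numeric matrix (one frame).
#' @param candidate list/row with 1-based `row`, `col` of the candidate
#'   pixel (as produced by [detect_spots()]).
#' @param window_px half-width of the fitting window in pixels (window is
#'   `2*window_px + 1` on a side); must fit inside the image.
#' @param pixel_size_nm pixel size for unit conversion.
#' @param sigma_bounds_px allowed fitted sigma range, pixels.
#' @param frame frame index carried into the output.
#' @param channel channel id carried into the output.
#' @return one-row data.frame (`frame`, `x_nm`, `y_nm`, `amplitude`
#'   (total photons), `offset`, `sigma_nm`, `residual` (RMS), `channel`,
#'   `ok`), or `ok = FALSE` (with `NA` estimates) when the window is clipped
#'   by the image edge, the optimizer fails, sigma leaves its bounds, or the
#'   amplitude is not positive (e.g. a candidate on flat background).
#' @export
fit_spot <- function(image, candidate, window_px = 5, pixel_size_nm = 160,
                     sigma_bounds_px = c(0.5, 4), frame = 1L, channel = 1L) {
  fail <- function() data.frame(frame = frame, x_nm = NA_real_, y_nm = NA_real_,
                                amplitude = NA_real_, offset = NA_real_,
                                sigma_nm = NA_real_, residual = NA_real_,
                                channel = channel, ok = FALSE)
  r0 <- as.integer(candidate$row); c0 <- as.integer(candidate$col)
  ny <- nrow(image); nx <- ncol(image)
  if (r0 - window_px < 1L || r0 + window_px > ny ||
      c0 - window_px < 1L || c0 + window_px > nx)
    return(fail())  # edge rejection
  rows <- (r0 - window_px):(r0 + window_px)
  cols <- (c0 - window_px):(c0 + window_px)
  patch <- image[rows, cols]

  offset0 <- min(patch)
  # centroid start
  w <- pmax(patch - offset0, 0)
  sw <- sum(w)
  x00 <- if (sw > 0) sum(t(w) * (cols - 0.5)) / sw else c0 - 0.5
  y00 <- if (sw > 0) sum(w * (rows - 0.5)) / sw else r0 - 0.5
  n_px <- length(patch)
  # amplitude and offset are linear: profile them out and optimize only
  # (x0, y0, log sigma) -- far more stable than a joint 5-parameter fit
  lin_fit <- function(par) {
    G <- int_gauss_patch(rows, cols, par[1], par[2], exp(par[3]))
    gm <- mean(G)
    vg <- sum((G - gm)^2)
    if (vg < .Machine$double.eps) return(NULL)
    amp <- sum((G - gm) * (patch - mean(patch))) / vg
    off <- mean(patch) - amp * gm
    list(amp = amp, off = off, rss = sum((patch - off - amp * G)^2))
  }
  obj <- function(par) {
    lf <- lin_fit(par)
    if (is.null(lf)) return(sum((patch - mean(patch))^2))
    lf$rss
  }
  fit <- try(stats::optim(c(x00, y00, log(1.1)), obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(fail())
  p <- fit$par
  lf <- lin_fit(p)
  if (is.null(lf)) return(fail())
  sigma <- exp(p[3]); amp <- lf$amp
  if (!is.finite(sigma) || sigma < sigma_bounds_px[1] ||
      sigma > sigma_bounds_px[2])
    return(fail())
  if (!is.finite(amp) || amp <= 0) return(fail())
  if (p[1] < cols[1] - 1 || p[1] > cols[length(cols)] ||
      p[2] < rows[1] - 1 || p[2] > rows[length(rows)])
    return(fail())
  rms <- sqrt(fit$value / n_px)
  # reject fits indistinguishable from a flat window: amplitude must rise
  # above the residual fluctuation level
  peak <- amp / (2 * pi * sigma^2)
  if (peak < 2 * max(rms, 1e-12)) return(fail())
  data.frame(frame = frame, x_nm = p[1] * pixel_size_nm,
             y_nm = p[2] * pixel_size_nm, amplitude = amp, offset = lf$off,
             sigma_nm = sigma * pixel_size_nm, residual = rms,
             channel = channel, ok = TRUE)
}

#' Detect and fit all spots in a movie
#'
#' Runs [detect_spots()] + [fit_spot()] frame by frame.
#'
#' @param movie array `[ny, nx, n_frames]` or a single matrix.
#' @param cfg a [sim_config()] supplying pixel size and PSF sigma.
#' @param threshold_k,min_separation_px,window_px see [detect_spots()] and
#'   [fit_spot()].
#' @param channel channel id stamped on the output.
#' @return data.frame of successful [fit_spot()] rows.
#' @export
locate_spots <- function(movie, cfg, threshold_k = 5, min_separation_px = 3,
                         window_px = 5, channel = 1L) {
  if (is.matrix(movie)) movie <- array(movie, c(dim(movie), 1L))
  psf_px <- cfg$psf_sigma_nm / cfg$pixel_size_nm
  out <- list()
  for (f in seq_len(dim(movie)[3])) {
    cand <- detect_spots(movie[, , f], threshold_k, min_separation_px, psf_px)
    for (i in seq_len(nrow(cand))) {
      s <- fit_spot(movie[, , f], cand[i, ], window_px = window_px,
                    pixel_size_nm = cfg$pixel_size_nm, frame = f,
                    channel = channel)
      if (s$ok) out[[length(out) + 1L]] <- s
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                      amplitude = numeric(), offset = numeric(),
                      sigma_nm = numeric(), residual = numeric(),
                      channel = integer(), ok = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link detections into tracks
#'
#' Frame-by-frame greedy nearest-neighbor assignment: at each frame, all
#' (active track end, new detection) pairs within `max_disp_nm` are sorted by
#' distance and matched one-to-one, closest first (deterministic given the
#' input order). A track stays active for `max_gap_frames` missed frames;
#' unmatched detections start new tracks.
#'
#' @param detections data.frame with `frame`, `x_nm`, `y_nm` (plus any other
#'   columns, carried through), sorted or not.
#' @param max_disp_nm maximum frame-to-frame displacement, nm.
#' @param max_gap_frames tolerated missed frames inside a track.
#' @return the input with a `track_id` column, ordered by track then frame.
#' @export
link_tracks <- function(detections, max_disp_nm = 640, max_gap_frames = 2) {
  if (nrow(detections) == 0L) {
    detections$track_id <- integer()
    return(detections)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  n_tracks <- 0L
  # active track registry: id, last x/y, last frame
  act <- data.frame(id = integer(), x = numeric(), y = numeric(),
                    last = integer())
  for (f in sort(unique(det$frame))) {
    act <- act[f - act$last <= max_gap_frames + 1L, , drop = FALSE]
    rows <- which(det$frame == f)
    if (nrow(act) > 0L && length(rows) > 0L) {
      d <- sqrt(outer(act$x, det$x_nm[rows], "-")^2 +
                  outer(act$y, det$y_nm[rows], "-")^2)
      ord <- order(d)
      used_t <- logical(nrow(act)); used_d <- logical(length(rows))
      for (k in ord) {
        if (d[k] > max_disp_nm) break
        i <- (k - 1L) %% nrow(act) + 1L
        j <- (k - 1L) %/% nrow(act) + 1L
        if (used_t[i] || used_d[j]) next
        used_t[i] <- TRUE; used_d[j] <- TRUE
        det$track_id[rows[j]] <- act$id[i]
        act$x[i] <- det$x_nm[rows[j]]; act$y[i] <- det$y_nm[rows[j]]
        act$last[i] <- f
      }
      new_rows <- rows[!used_d]
    } else new_rows <- rows
    for (j in new_rows) {
      n_tracks <- n_tracks + 1L
      det$track_id[j] <- n_tracks
      act <- rbind(act, data.frame(id = n_tracks, x = det$x_nm[j],
                                   y = det$y_nm[j], last = f))
    }
  }
  det[order(det$track_id, det$frame), , drop = FALSE]
}
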