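test_that("blank noise frames yield (almost) no false candidates", {
  set.seed(21)
  false_pos <- vapply(1:5, function(i) {
    img <- matrix(rnorm(250 * 250, mean = 10, sd = 2), 250, 250)
    nrow(detect_spots(img, threshold_k = 5, min_separation_px = 3))
  }, numeric(1))
  # a 5-sigma threshold on a smoothed field: tail expectation well below
  # one candidate per frame on average
  expect_lt(mean(false_pos), 1)
})

test_that("rendered spots are detected at their brightest pixel", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  em <- data.frame(x_nm = 2000, y_nm = 1800, photons = 4000)
  img <- render_frame(em, cfg, noise = FALSE)
  set.seed(1)
  img <- img + matrix(rnorm(length(img), sd = 0.1), nrow(img))
  cand <- detect_spots(img, 5, 3, psf_sigma_px = cfg$psf_sigma_nm / 160)
  expect_identical(nrow(cand), 1L)
  # brightest pixel of the spot: center position 2000 nm -> column 13
  expect_identical(cand$col, 13L)
  expect_identical(cand$row, 12L)  # 1800 nm falls in pixel 12
})

test_that("min_separation keeps distinct nearby maxima apart", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  em <- data.frame(x_nm = c(1200, 1200 + 10 * 160), y_nm = c(2000, 2000),
                   photons = c(4000, 3000))
  img <- render_frame(em, cfg, noise = FALSE)
  set.seed(2)
  img <- img + matrix(rnorm(length(img), sd = 0.1), nrow(img))
  cand <- detect_spots(img, 5, 3)
  expect_identical(nrow(cand), 2L)
  # brute-force oracle: strict maxima above threshold, distance-pruned
  expect_identical(sort(cand$col), c(8L, 18L))
})

test_that("noiseless PSF fits recover the center to sub-millipixel", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  for (xy in list(c(2013, 1787), c(1960, 2080), c(2000.4, 1999.7))) {
    em <- data.frame(x_nm = xy[1], y_nm = xy[2], photons = 3000)
    img <- render_frame(em, cfg, noise = FALSE)
    cand <- detect_spots(img + 1e-3 * matrix(rnorm(length(img)), nrow(img)),
                         5, 3)
    s <- fit_spot(img, cand[1, ], window_px = 5)
    expect_true(s$ok)
    expect_lt(abs(s$x_nm - xy[1]) / 160, 1e-3)
    expect_lt(abs(s$y_nm - xy[2]) / 160, 1e-3)
    expect_equal(s$amplitude, 3000, tolerance = 1e-3)
    expect_equal(s$sigma_nm, cfg$psf_sigma_nm, tolerance = 1e-3)
  }
})

test_that("fits fail cleanly on flat windows and clipped edges", {
  img <- matrix(10, 30, 30)
  flat <- fit_spot(img, list(row = 15, col = 15), window_px = 5)
  expect_false(flat$ok)
  edge <- fit_spot(img, list(row = 2, col = 15), window_px = 5)
  expect_false(edge$ok)
})

test_that("localization is unbiased and near the photon-limited precision", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  n_photons <- 2000
  em <- data.frame(x_nm = 2012, y_nm = 1790, photons = n_photons)
  expected <- render_frame(em, cfg, noise = FALSE)
  set.seed(31)
  reps <- 150
  est <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    noisy <- matrix(rpois(length(expected), expected), nrow(expected))
    s <- fit_spot(noisy, list(row = 12, col = 13), window_px = 5)
    if (s$ok) est[i, ] <- c(s$x_nm, s$y_nm)
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  expect_gt(nrow(est), 0.9 * reps)
  # unbiased: mean signed error < 0.05 px
  expect_lt(abs(mean(est[, 1]) - 2012) / 160, 0.05)
  expect_lt(abs(mean(est[, 2]) - 1790) / 160, 0.05)
  # precision within 2x of the sigma/sqrt(N) shot-noise scaling
  limit <- cfg$psf_sigma_nm / sqrt(n_photons)
  expect_lt(sd(est[, 1]), 2 * limit * sqrt(2))
  expect_gt(sd(est[, 1]), limit / 2)
})

test_that("an immobile emitter links into one full-length track", {
  det <- data.frame(frame = 1:100, x_nm = 2000 + rnorm(100, sd = 5),
                    y_nm = 1500 + rnorm(100, sd = 5))
  tr <- link_tracks(det, max_disp_nm = 640)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 100L)
})

test_that("well-separated emitters never merge", {
  det <- rbind(data.frame(frame = 1:50, x_nm = 1000, y_nm = 1000),
               data.frame(frame = 1:50, x_nm = 9000, y_nm = 9000))
  tr <- link_tracks(det, max_disp_nm = 640)
  expect_identical(length(unique(tr$track_id)), 2L)
  by_track <- split(tr$x_nm, tr$track_id)
  expect_true(all(vapply(by_track, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("a moving emitter below max_disp forms one faithful track", {
  cfg <- tiny_cfg(field_um = 16, n_frames = 40)
  p <- straight_path(length_um = 12, y_um = 8)
  truth <- mover_tracks(p, v_nms = 500, t_on = 2, t_off = 20, cfg)
  det <- truth[, c("frame", "x_nm", "y_nm")]
  det$x_nm <- det$x_nm + rnorm(nrow(det), sd = 10)
  tr <- link_tracks(det, max_disp_nm = 640)
  expect_identical(length(unique(tr$track_id)), 1L)
  # displacement series matches truth within the localization error
  expect_lt(max(abs(tr$x_nm - truth$x_nm)), 50)
})

test_that("gap closing bridges short disappearances; long ones split", {
  det <- data.frame(frame = c(1:10, 13:20), x_nm = 1000, y_nm = 1000)
  tr2 <- link_tracks(det, max_disp_nm = 640, max_gap_frames = 2)
  expect_identical(length(unique(tr2$track_id)), 1L)
  tr0 <- link_tracks(det, max_disp_nm = 640, max_gap_frames = 0)
  expect_identical(length(unique(tr0$track_id)), 2L)
})

test_that("every detection lands in exactly one track", {
  set.seed(4)
  det <- data.frame(frame = rep(1:20, each = 5),
                    x_nm = runif(100, 0, 20000),
                    y_nm = runif(100, 0, 20000))
  tr <- link_tracks(det, max_disp_nm = 1500)
  expect_identical(nrow(tr), nrow(det))
  expect_false(any(is.na(tr$track_id)))
  # partition: (frame, position) rows preserved exactly once
  key <- paste(tr$frame, round(tr$x_nm, 6), round(tr$y_nm, 6))
  expect_identical(sort(key),
                   sort(paste(det$frame, round(det$x_nm, 6),
                              round(det$y_nm, 6))))
})

test_that("locate_spots finds and fits movie spots end to end", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 3, seed = 8)
  em <- data.frame(x_nm = 2000, y_nm = 2000, photons = 3000)
  movie <- array(0, c(cfg$n_pixels[2], cfg$n_pixels[1], 3))
  set.seed(8)
  for (f in 1:3) movie[, , f] <- render_frame(em, cfg, noise = TRUE)
  spots <- locate_spots(movie, cfg)
  expect_identical(nrow(spots), 3L)
  expect_true(all(abs(spots$x_nm - 2000) < 50))
})
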