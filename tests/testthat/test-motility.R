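test_that("microtubule length filter is inclusive at the cutoff", {
  paths <- list(straight_path(8, y_um = 2, id = 1),
                straight_path(10, y_um = 4, id = 2),
                straight_path(15, y_um = 6, id = 3))
  kept <- filter_microtubules(paths, 10)
  expect_identical(vapply(kept, function(p) p$id, numeric(1)), c(2, 3))
  expect_identical(filter_microtubules(list(), 10), list())
  expect_warning(out <- filter_microtubules(paths[1], 10), "none retained")
  expect_identical(out, list())
})

test_that("kymograph of an immobile emitter is a constant vertical line", {
  cfg <- tiny_cfg(field_um = 8, n_frames = 10)
  p <- straight_path(length_um = 6, y_um = 4)
  em <- data.frame(x_nm = 3000, y_nm = 4000, photons = 4000)
  movie <- array(0, c(cfg$n_pixels[2], cfg$n_pixels[1], cfg$n_frames))
  for (f in seq_len(cfg$n_frames))
    movie[, , f] <- render_frame(em, cfg, noise = FALSE)
  ky <- build_kymograph(movie, p, cfg, width_px = 3)
  expect_identical(nrow(ky$intensity), cfg$n_frames)
  expect_identical(ncol(ky$intensity),
                   as.integer(ceiling(p$length_nm / ky$bin_nm)))
  peak_bin <- apply(ky$intensity, 1, which.max)
  expect_true(all(peak_bin == peak_bin[1]))
  # arc of emitter: x = 3000 on a path starting at x0 = 1000 -> arc 2000
  expect_lt(abs((peak_bin[1] - 0.5) * ky$bin_nm - 2000), ky$bin_nm)
  # all rows identical for a static scene
  expect_lt(max(abs(sweep(ky$intensity, 2, ky$intensity[1, ]))), 1e-9)
})

test_that("a constant-velocity mover traces the expected kymograph slope", {
  cfg <- tiny_cfg(field_um = 16, n_frames = 30)
  p <- straight_path(length_um = 14, y_um = 8)
  v <- 600
  tf <- (seq_len(cfg$n_frames) - 0.5) * cfg$frame_interval_s
  movie <- array(0, c(cfg$n_pixels[2], cfg$n_pixels[1], cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    em <- data.frame(x_nm = 1000 + 500 + v * tf[f], y_nm = 8000,
                     photons = 4000)
    movie[, , f] <- render_frame(em, cfg, noise = FALSE)
  }
  ky <- build_kymograph(movie, p, cfg)
  peak_arc <- (apply(ky$intensity, 1, which.max) - 0.5) * ky$bin_nm
  truth_arc <- 500 + v * tf
  expect_lt(max(abs(peak_arc - truth_arc)), ky$bin_nm)
  # fitted slope = velocity
  slope <- coef(lm(peak_arc ~ tf))[2]
  expect_equal(unname(slope), v, tolerance = 0.02)
})

test_that("blank movies give all-background kymographs and paths must fit", {
  cfg <- tiny_cfg(field_um = 8, n_frames = 4)
  movie <- array(7, c(cfg$n_pixels[2], cfg$n_pixels[1], 4))
  p <- straight_path(length_um = 6, y_um = 4)
  ky <- build_kymograph(movie, p, cfg)
  expect_true(all(abs(ky$intensity - 7) < 1e-12))
  long <- mt_path(rbind(c(100, 4000), c(8100, 4000)))
  expect_error(build_kymograph(movie, long, cfg), "exits")
})

test_that("static and diffusive binders produce no runs", {
  cfg <- tiny_cfg(field_um = 16, n_frames = 160)
  p <- straight_path(length_um = 12, y_um = 8)
  xy <- path_point(p, 4000)
  static <- data.frame(track_id = 1L, frame = 1:150,
                       x_nm = xy[1], y_nm = xy[2])
  expect_identical(nrow(detect_runs(static, p, 0.6,
                                    acquisition_frames = 160)), 0L)
  # static binder seen through localization jitter (40 nm rms)
  set.seed(5)
  jitter_arc <- 4000 + rnorm(150, 0, 40)
  dxy <- path_point(p, jitter_arc)
  jittery <- data.frame(track_id = 2L, frame = 1:150,
                        x_nm = dxy[, 1], y_nm = dxy[, 2])
  expect_identical(nrow(detect_runs(jittery, p, 0.6,
                                    acquisition_frames = 160)), 0L)
})

test_that("truth runs are recovered with velocity within tolerance", {
  cfg <- tiny_cfg(field_um = 16, n_frames = 100)
  p <- straight_path(length_um = 12, y_um = 8)
  # 3 um at 500 nm/s starting mid-movie, away from all edges
  tr <- mover_tracks(p, v_nms = 500, t_on = 10, t_off = 16, cfg,
                     arc_on = 3000)
  runs <- detect_runs(tr, p, cfg$frame_interval_s, acquisition_frames = 100)
  expect_identical(nrow(runs), 1L)
  expect_false(runs$censored)
  expect_equal(runs$velocity_nms, 500, tolerance = 0.1)
  expect_identical(runs$direction, 1L)
  expect_equal(runs$displacement_nm, 3000, tolerance = 0.15)
  # two temporally separated movers on one filament -> two runs
  tr2 <- rbind(tr, transform(mover_tracks(p, 500, t_on = 40, t_off = 46,
                                          cfg, arc_on = 6000),
                             track_id = 2L))
  runs2 <- detect_runs(tr2, p, cfg$frame_interval_s,
                       acquisition_frames = 100)
  expect_identical(nrow(runs2), 2L)
})

test_that("reversed travel keeps speed and flips direction", {
  cfg <- tiny_cfg(field_um = 16, n_frames = 100)
  p <- straight_path(length_um = 12, y_um = 8)
  tf <- (1:100 - 0.5) * cfg$frame_interval_s
  fr <- which(tf >= 10 & tf <= 16)
  arc <- 9000 - 500 * (tf[fr] - 10)
  xy <- path_point(p, arc)
  tr <- data.frame(track_id = 1L, frame = fr, x_nm = xy[, 1], y_nm = xy[, 2])
  runs <- detect_runs(tr, p, cfg$frame_interval_s, acquisition_frames = 100)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$direction, -1L)
  expect_equal(runs$velocity_nms, 500, tolerance = 0.1)
})

test_that("run frequency is count over length times duration, per filament", {
  p20 <- straight_path(20, y_um = 10, id = "mt1")
  runs <- data.frame(path_id = rep("mt1", 10))
  fr <- run_frequency(runs, list(p20), duration_s = 300)
  expect_equal(fr$per_mt$frequency, 10 / (20 * 300))
  expect_equal(fr$mean, 1.6667e-3, tolerance = 1e-4)
  # zero runs anywhere: mean 0, sd 0
  fr0 <- run_frequency(runs[0, , drop = FALSE],
                       list(p20, straight_path(15, y_um = 5, id = "mt2")),
                       300)
  expect_identical(fr0$mean, 0)
  expect_identical(fr0$sd, 0)
  expect_identical(fr0$n_mt, 2L)
  expect_error(run_frequency(runs, list(p20), 0), "> 0")
  expect_error(run_frequency(data.frame(path_id = "ghost"), list(p20), 300),
               "absent")
})

test_that("normalization maps the reference to exactly 1", {
  p <- straight_path(20, y_um = 10, id = "a")
  mk <- function(n) run_frequency(data.frame(path_id = rep("a", n)),
                                  list(p), 300)
  ref <- mk(4)
  expect_equal(normalize_frequency(ref, ref)$fold_mean, 1)
  # 16-fold regime: 3.2e-3 vs 2e-4
  r16 <- structure(list(per_mt = data.frame(frequency = 3.2e-3),
                        mean = 3.2e-3, sd = 0, n_mt = 1L),
                   class = "frequency_result")
  ref2 <- structure(list(per_mt = data.frame(frequency = 2e-4),
                         mean = 2e-4, sd = 0, n_mt = 1L),
                    class = "frequency_result")
  expect_equal(normalize_frequency(r16, ref2)$fold_mean, 16)
  expect_equal(normalize_frequency(mk(0), ref)$fold_mean, 0)
  expect_error(normalize_frequency(ref, mk(0)), "> 0")
})

test_that("velocity arithmetic and truth consistency", {
  runs <- data.frame(arc_start = 0, arc_end = 3000, t_start = 1, t_end = 7)
  expect_equal(run_velocity(runs), 500)
  # zero-spread truth: recovered velocities exactly the configured value
  cfg <- tiny_cfg(field_um = 32, n_frames = 200, seed = 12)
  p <- straight_path(25, y_um = 16)
  sim <- simulate_motility_movie(cfg, p, 3e-3, velocity_sd_nms = 0,
                                 render = "none")
  tr <- truth_tracks(sim$truth, cfg)
  runs2 <- detect_runs(tr, p, cfg$frame_interval_s,
                       acquisition_frames = cfg$n_frames)
  v <- run_velocity(runs2[!runs2$censored, ])
  expect_gt(length(v), 0)
  expect_lt(max(abs(v - 500)) / 500, 0.02)
})

test_that("frequency recovery is unbiased and linear in the landing rate", {
  cfg <- sim_config(frame_interval_s = 0.6, n_frames = 500)
  recover <- function(f_true, seeds) {
    vapply(seeds, function(s) {
      cfg$rng_seed <- s
      set.seed(s)
      paths <- lapply(1:10, function(i)
        straight_path(runif(1, 15, 30), y_um = 3.5 * i, id = i))
      sim <- simulate_motility_movie(cfg, paths, f_true, render = "none")
      analyze_motility(truth_tracks(sim$truth, cfg), paths, cfg,
                       params = list(min_mt_length_um = 10))$frequency$mean
    }, numeric(1))
  }
  # unbiasedness at one rate (3 MC s.e.; the acceptance suite tightens this)
  f0 <- 2e-3
  rec <- recover(f0, 1:40)
  expect_lt(abs(mean(rec) - f0), 3 * sd(rec) / sqrt(length(rec)))
  # linearity across rates: slope of recovered vs truth = 1 +/- 0.05
  rates <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)
  means <- vapply(rates, function(f) mean(recover(f, 1:12)), numeric(1))
  slope <- unname(coef(lm(means ~ rates))[2])
  expect_lt(abs(slope - 1), 0.05)
})

test_that("dropping short microtubules never changes retained values", {
  cfg <- sim_config(frame_interval_s = 0.6, n_frames = 500, rng_seed = 77)
  set.seed(77)
  paths <- c(lapply(1:6, function(i)
    straight_path(runif(1, 12, 25), y_um = 3 + 5 * i, id = i)),
    list(straight_path(6, y_um = 36, id = 7L)))
  sim <- simulate_motility_movie(cfg, paths, 3e-3, render = "none")
  tr <- truth_tracks(sim$truth, cfg)
  with_short <- analyze_motility(tr, paths, cfg,
                                 params = list(min_mt_length_um = 0.1))
  without_short <- analyze_motility(tr, paths, cfg,
                                    params = list(min_mt_length_um = 10))
  a <- with_short$frequency$per_mt
  b <- without_short$frequency$per_mt
  shared <- intersect(a$path_id, b$path_id)
  expect_identical(a$frequency[match(shared, a$path_id)],
                   b$frequency[match(shared, b$path_id)])
})
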