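test_that("sim_config validates physical quantities", {
  expect_error(sim_config(pixel_size_nm = -1), "> 0")
  expect_error(sim_config(field_size_um = c(40.03, 40)), "whole number")
  expect_error(sim_config(em_gain = 0.5), ">= 1")
  cfg <- sim_config()
  expect_identical(cfg$n_pixels, c(250L, 250L))
  expect_equal(cfg$duration_s, 300)
})

test_that("render_frame integrates the PSF exactly and respects dark dyes", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  em <- data.frame(x_nm = 2013, y_nm = 1787, photons = 3000)
  img <- render_frame(em, cfg, noise = FALSE)
  # full Gaussian integral: summed signal above background = total photons
  expect_equal(sum(img - cfg$background_photons), 3000, tolerance = 1e-6)
  # zero-photon emitter contributes nothing
  em0 <- data.frame(x_nm = 2013, y_nm = 1787, photons = 0)
  expect_equal(render_frame(em0, cfg, noise = FALSE),
               render_frame(NULL, cfg, noise = FALSE))
  expect_true(all(img >= 0))
})

test_that("rendering is translation-equivariant to sub-pixel shifts", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 1)
  # shift by exactly one pixel: images must be identical up to the shift
  em1 <- data.frame(x_nm = 1800, y_nm = 2000, photons = 5000)
  em2 <- data.frame(x_nm = 1800 + cfg$pixel_size_nm, y_nm = 2000,
                    photons = 5000)
  i1 <- render_frame(em1, cfg, noise = FALSE)
  i2 <- render_frame(em2, cfg, noise = FALSE)
  expect_lt(max(abs(i1[, 3:22] - i2[, 4:23])), 1e-9)
  # sub-pixel shift moves the photon-weighted centroid by exactly the shift
  for (dx in c(0.25, 0.5)) {
    em3 <- data.frame(x_nm = 1800 + dx * cfg$pixel_size_nm, y_nm = 2000,
                      photons = 5000)
    i3 <- render_frame(em3, cfg, noise = FALSE) - cfg$background_photons
    cx1 <- sum(t(i1 - cfg$background_photons) %*% rep(1, nrow(i1)) *
                 (seq_len(ncol(i1)) - 0.5)) / sum(i1 - cfg$background_photons)
    cx3 <- sum(t(i3) %*% rep(1, nrow(i3)) * (seq_len(ncol(i3)) - 0.5)) /
      sum(i3)
    expect_equal(cx3 - cx1, dx, tolerance = 1e-6)
  }
})

test_that("EM gain scales the expected signal linearly", {
  cfg1 <- tiny_cfg(field_um = 4, n_frames = 1, seed = 5)
  cfg2 <- tiny_cfg(field_um = 4, n_frames = 1, seed = 5, em_gain = 2)
  em <- data.frame(x_nm = 1000, y_nm = 1000, photons = 2000)
  set.seed(5)
  m1 <- mean(replicate(200, sum(render_frame(em, cfg1, noise = TRUE))))
  set.seed(5)
  m2 <- mean(replicate(200, sum(render_frame(em, cfg2, noise = TRUE))))
  expect_equal(m2 / m1, 2, tolerance = 0.02)
})

test_that("zero landing rate gives background-only truth", {
  cfg <- tiny_cfg(n_frames = 5)
  p <- straight_path(length_um = 5, cfg = cfg)
  sim <- simulate_motility_movie(cfg, p, f_true = 0, render = "full")
  expect_identical(nrow(sim$truth$runs), 0L)
  # movie is pure noise around the background level
  expect_lt(abs(mean(sim$movie) - cfg$background_photons), 1)
})

test_that("landing statistics are Poisson with mean f * L * T", {
  cfg <- sim_config(field_size_um = c(40, 40), frame_interval_s = 0.6,
                    n_frames = 500)
  p <- straight_path(length_um = 25, y_um = 20, id = 1L)
  lambda <- 2e-3 * 25 * 300  # = 15
  counts <- vapply(1:500, function(s) {
    cfg$rng_seed <- s
    nrow(simulate_motility_movie(cfg, p, 2e-3, render = "none")$truth$runs)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 500))
  # Poisson dispersion: chi-square GOF on binned counts at alpha = 0.01
  qs <- unique(qpois(seq(0.1, 0.9, 0.1), lambda))
  breaks <- c(-Inf, qs, Inf)
  obs <- as.numeric(table(cut(counts, breaks)))
  expj <- diff(ppois(breaks, lambda)) * 500
  chi2 <- sum((obs - expj)^2 / expj)
  expect_lt(chi2, qchisq(0.99, df = length(expj) - 1))
})

test_that("degenerate velocity spread yields identical run velocities", {
  cfg <- tiny_cfg(field_um = 32, n_frames = 100, seed = 3)
  p <- straight_path(length_um = 25, y_um = 15)
  sim <- simulate_motility_movie(cfg, p, 5e-3, velocity_sd_nms = 0,
                                 render = "none")
  expect_gt(nrow(sim$truth$runs), 0)
  expect_true(all(sim$truth$runs$v_nms == 500))
})

test_that("simulator rejects invalid geometry and rates", {
  cfg <- tiny_cfg()
  outside <- mt_path(rbind(c(-100, 4000), c(5000, 4000)))
  expect_error(simulate_motility_movie(cfg, outside, 1e-3), "outside")
  p <- straight_path(length_um = 5, cfg = cfg)
  expect_error(simulate_motility_movie(cfg, p, -1), ">= 0")
  expect_error(simulate_binding_movie(cfg, tau_s = -2), "> 0")
})

test_that("binding truth has exponential, non-overlapping, censored dwells", {
  cfg <- sim_config(field_size_um = c(40, 40), frame_interval_s = 1,
                    n_frames = 5000, rng_seed = 9)
  sim <- simulate_binding_movie(cfg, n_baits = 120, tau_s = 21,
                                gap_mean_s = 20, render = "none")
  ev <- sim$truth$events
  expect_gt(nrow(ev), 1e4)
  # per-bait episodes never overlap
  for (b in unique(ev$bait_id[duplicated(ev$bait_id)])) {
    e <- ev[ev$bait_id == b, ]
    e <- e[order(e$t_on), ]
    expect_true(all(diff(as.vector(rbind(e$t_on, e$t_off))) >= 0))
  }
  # uncensored dwells follow the configured exponential (KS, alpha = 0.01)
  d <- (ev$t_off - ev$t_on)[!ev$censored]
  d <- d[seq_len(1e4)]
  expect_gt(suppressWarnings(ks.test(d, "pexp", 1 / 21))$p.value, 0.01)
  expect_lt(abs(mean(d) - 21), 3 * 21 / sqrt(length(d)))
  # censored episodes end exactly at acquisition end
  expect_true(all(ev$t_off[ev$censored] == cfg$duration_s))
})

test_that("dwells far beyond the acquisition are all censored", {
  cfg <- tiny_cfg(n_frames = 10, seed = 4)
  sim <- simulate_binding_movie(cfg, n_baits = 30, tau_s = 1e6,
                                gap_mean_s = 2, render = "none")
  expect_true(all(sim$truth$events$censored))
  # zero baits: empty truth
  sim0 <- simulate_binding_movie(cfg, n_baits = 0, render = "none")
  expect_identical(nrow(sim0$truth$events), 0L)
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 3, seed = 123)
  p <- straight_path(length_um = 3, y_um = 2, x0_um = 0.5)
  s1 <- simulate_motility_movie(cfg, p, 5e-3, render = "full")
  s2 <- simulate_motility_movie(cfg, p, 5e-3, render = "full")
  expect_identical(s1$truth$runs, s2$truth$runs)
  expect_identical(s1$movie, s2$movie)
})

test_that("mass sampling matches component moments", {
  mix <- data.frame(location = 200, scale = 20, shape = 0, weight = 1)
  x <- sample_masses(mix, 2e4, seed = 6)
  expect_lt(abs(mean(x) - 200), 3 * 20 / sqrt(2e4))
  expect_lt(abs(sd(x) - 20), 1)
  skew <- mean(((x - mean(x)) / sd(x))^3)
  expect_lt(abs(skew), 0.06)  # symmetric component: 3 s.e. of sample skewness
  # degenerate weights route all samples to component 1
  mix2 <- data.frame(location = c(100, 300), scale = c(10, 10),
                     shape = c(0, 0), weight = c(1, 0))
  x2 <- sample_masses(mix2, 500, seed = 7)
  expect_true(all(attr(x2, "component") == 1L))
  expect_error(sample_masses(data.frame(), 10), "non-empty")
})

test_that("skewed components reproduce the skew-normal mean formula", {
  m <- skewnorm_moments(100, 15, 4)
  x <- rskewnorm(5e4, 100, 15, 4)
  expect_lt(abs(mean(x) - m$mean), 3 * m$sd / sqrt(5e4))
  expect_lt(abs(sd(x) - m$sd), 0.5)
})

test_that("write_simulation lays out movies, truth and config", {
  cfg <- tiny_cfg(field_um = 4, n_frames = 2, seed = 5)
  p <- straight_path(length_um = 3, y_um = 2, x0_um = 0.5)
  sim <- simulate_motility_movie(cfg, p, 5e-3, render = "full")
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(d, c("runs.csv", "paths.csv",
                                             "config.yaml",
                                             "movie_ch1.tif")))))
  back <- read_tiff_stack(file.path(d, "movie_ch1.tif"))
  expect_equal(dim(back), dim(sim$movie))
})
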