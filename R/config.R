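#' Simulation configuration
#'
#' Bundles the imaging geometry and noise model used by every simulator and
#' renderer in the package. Defaults emulate a typical objective-type TIRF
#' setup with an EMCCD detector: a 40 x 40 micrometer field imaged at
#' 160 nm/pixel, 500 frames over a 5 minute acquisition.
#'
#' @param field_size_um numeric length-2, field width/height in micrometers.
#' @param pixel_size_nm camera pixel size after magnification, nanometers.
#' @param frame_interval_s time between frames, seconds.
#' @param n_frames number of frames in the acquisition.
#' @param psf_sigma_nm standard deviation of the (isotropic, integrated)
#'   Gaussian point-spread function, nanometers.
#' @param photon_rate_per_dye expected photons per dye per second.
#' @param background_photons expected background photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param em_gain electron-multiplying gain (unitless multiplier, >= 1).
#'   Gains above 1 add the usual EM excess noise (variance doubling).
#' @param bleach_tau_s mean single-dye photobleaching time in seconds, or
#'   `Inf` (default) to disable bleaching.
#' @param rng_seed integer seed fixing every downstream draw, or `NULL`.
#'
#' @return an object of class `sim_config` (a validated list); its
#'   `n_pixels` field gives the integer field size in pixels.
#' @examples
#' cfg <- sim_config(frame_interval_s = 0.6, n_frames = 10)
#' cfg$n_pixels
#' @export
sim_config <- function(field_size_um = c(40, 40),
                       pixel_size_nm = 160,
                       frame_interval_s = 0.6,
                       n_frames = 500,
                       psf_sigma_nm = 170,
                       photon_rate_per_dye = 500,
                       background_photons = 10,
                       read_noise_sd = 2,
                       em_gain = 1,
                       bleach_tau_s = Inf,
                       rng_seed = NULL) {
  if (length(field_size_um) == 1L) field_size_um <- rep(field_size_um, 2L)
  if (length(field_size_um) != 2L || any(!is.finite(field_size_um)) ||
      any(field_size_um <= 0))
    stopf("'field_size_um' must be one or two positive numbers")
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  assert_scalar_num(n_frames, "n_frames", positive = TRUE)
  assert_scalar_num(psf_sigma_nm, "psf_sigma_nm", positive = TRUE)
  assert_scalar_num(photon_rate_per_dye, "photon_rate_per_dye", nonneg = TRUE)
  assert_scalar_num(background_photons, "background_photons", nonneg = TRUE)
  assert_scalar_num(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  assert_scalar_num(em_gain, "em_gain", positive = TRUE)
  if (em_gain < 1) stopf("'em_gain' must be >= 1")
  if (!identical(bleach_tau_s, Inf))
    assert_scalar_num(bleach_tau_s, "bleach_tau_s", positive = TRUE)

  n_px <- field_size_um * 1000 / pixel_size_nm
  if (any(abs(n_px - round(n_px)) > 1e-9))
    stopf("field size (%g x %g um) is not a whole number of %g-nm pixels",
          field_size_um[1], field_size_um[2], pixel_size_nm)

  structure(list(
    field_size_um = as.numeric(field_size_um),
    field_size_nm = as.numeric(field_size_um) * 1000,
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(round(n_frames)),
    duration_s = frame_interval_s * round(n_frames),
    psf_sigma_nm = psf_sigma_nm,
    photon_rate_per_dye = photon_rate_per_dye,
    background_photons = background_photons,
    read_noise_sd = read_noise_sd,
    em_gain = em_gain,
    bleach_tau_s = bleach_tau_s,
    n_pixels = as.integer(round(n_px)),
    rng_seed = rng_seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "TIRF simulation config: %g x %g um field (%d x %d px @ %g nm)\n",
    x$field_size_um[1], x$field_size_um[2],
    x$n_pixels[1], x$n_pixels[2], x$pixel_size_nm))
  cat(sprintf("  %d frames x %g s = %g s; PSF sigma %g nm\n",
              x$n_frames, x$frame_interval_s, x$duration_s, x$psf_sigma_nm))
  cat(sprintf(
    "  photons/dye/s %g; background %g/px/frame; read noise %g; EM gain %g\n",
    x$photon_rate_per_dye, x$background_photons, x$read_noise_sd, x$em_gain))
  invisible(x)
}

#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
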