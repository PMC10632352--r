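# Mass photometry: contrast-to-mass calibration and skew-normal mixture
# deconvolution of mass histograms.
#
# EM follows the standard hierarchical representation of the Azzalini
# skew-normal, y = xi + Delta*t + e with t half-normal and e ~ N(0, Gamma):
# the E-step uses exact truncated-normal moments of t | y, and the M-step
# updates (xi, Delta, Gamma) by conditional maximization, so the observed
# log-likelihood is nondecreasing every iteration (asserted).

#' Calibrate contrast to mass
#'
#' Ordinary least-squares line mapping instrument contrast to molecular
#' mass (kDa), from standards of known mass (e.g. a conalbumin / aldolase /
#' thyroglobulin mix).
#'
#' @param contrast_means measured mean contrasts of the standards (>= 2).
#' @param known_masses their known masses, kDa.
#' @return object of class `mp_calibration`: `slope` (kDa per contrast
#'   unit), `intercept` (kDa), `residual_rms`, `standards` data.frame, and
#'   `predict(cal, contrast)` support via [predict.mp_calibration()].
#' @export
mp_calibrate <- function(contrast_means, known_masses) {
  if (length(contrast_means) < 2L || length(contrast_means) != length(known_masses))
    stopf("need >= 2 (contrast, mass) pairs of equal length")
  if (stats::sd(contrast_means) == 0)
    stopf("calibration contrasts are identical; line is undetermined")
  fit <- stats::lm(known_masses ~ contrast_means)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    standards = data.frame(contrast = contrast_means, mass_kda = known_masses)),
    class = "mp_calibration")
}

#' @rdname mp_calibrate
#' @param object an `mp_calibration`.
#' @param contrast contrasts to convert.
#' @param ... unused.
#' @export
predict.mp_calibration <- function(object, contrast, ...) {
  object$intercept + object$slope * contrast
}

# log mixture density, n x K matrix of per-component log(pi_k f_k)
#' @noRd
sn_mix_logdens <- function(x, comp) {
  K <- nrow(comp)
  sapply(seq_len(K), function(k)
    log(comp$weight[k]) + dskewnorm(x, comp$location[k], comp$scale[k],
                                    comp$shape[k], log = TRUE))
}

#' @noRd
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a skew-normal mixture to mass samples
#'
#' Maximum-likelihood deconvolution of a mass histogram into K skewed
#' Gaussian populations via EM (exact conditional-moment E-step, conditional
#' M-step), with multiple random restarts; the best restart by final
#' log-likelihood wins. Components are reported sorted by location, which
#' resolves label switching deterministically. Each component's mean mass
#' is the distribution mean `location + scale * delta * sqrt(2/pi)` with
#' `delta = shape / sqrt(1 + shape^2)`.
#'
#' @param masses numeric vector of masses (kDa).
#' @param K number of components (>= 1).
#' @param shape_fixed fix all shapes to this value (e.g. 0 for a plain
#'   Gaussian mixture) instead of estimating them; `NULL` estimates.
#' @param restarts number of EM restarts (k-means++-style initial
#'   locations).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed seed making the restarts deterministic.
#' @return object of class `sn_mixture`: `components` data.frame
#'   (`location`, `scale`, `shape`, `weight`, `mean_kda`, `sd_kda`),
#'   `loglik`, `loglik_trace` (of the winning restart), `n`, `K`,
#'   `n_iter`, `converged`.
#' @examples
#' x <- sample_masses(data.frame(location = 200, scale = 20, shape = 0,
#'                               weight = 1), 500, seed = 1)
#' fit_mixture(x, K = 1, shape_fixed = 0)
#' @export
fit_mixture <- function(masses, K, shape_fixed = NULL, restarts = 10,
                        max_iter = 500, tol = 1e-8, seed = 1) {
  x <- as.numeric(masses)
  if (any(!is.finite(x))) stopf("masses must be finite")
  if (K < 1) stopf("'K' must be >= 1")
  if (length(x) < 50 * K)
    warnf("only %d samples for %d components; fit may be unstable",
          length(x), K)
  set_seed_if(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- sn_mix_init(x, K, jitter = r > 1L)
    fit <- try(sn_mix_em(x, init, shape_fixed, max_iter, tol), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stopf("EM failed to converge in all %d restarts", restarts)
  comp <- best$components
  ord <- order(comp$location)
  comp <- comp[ord, , drop = FALSE]
  delta <- comp$shape / sqrt(1 + comp$shape^2)
  comp$mean_kda <- comp$location + comp$scale * delta * sqrt(2 / pi)
  comp$sd_kda <- comp$scale * sqrt(1 - 2 * delta^2 / pi)
  rownames(comp) <- NULL
  structure(list(components = comp, loglik = best$loglik,
                 loglik_trace = best$trace, n = length(x), K = K,
                 n_iter = best$n_iter, converged = best$converged),
            class = "sn_mixture")
}

# k-means++-style spread of initial locations over the sample
#' @noRd
sn_mix_init <- function(x, K, jitter = FALSE) {
  qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (jitter) qs <- qs + stats::rnorm(K, sd = stats::sd(x) / 4)
  data.frame(location = qs,
             scale = rep(stats::sd(x) / max(K, 2), K),
             shape = if (jitter) stats::rnorm(K, sd = 0.5) else rep(0, K),
             weight = rep(1 / K, K))
}

#' @noRd
sn_mix_em <- function(x, comp, shape_fixed, max_iter, tol) {
  n <- length(x)
  scale_floor <- max(stats::sd(x) * 1e-4, .Machine$double.eps)
  if (!is.null(shape_fixed)) comp$shape <- rep(shape_fixed, nrow(comp))
  ld <- sn_mix_logdens(x, comp)
  ll <- sum(logsumexp_rows(ld))
  trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities + truncated-normal moments of the latent t
    z <- exp(ld - logsumexp_rows(ld))
    for (k in seq_len(nrow(comp))) {
      om <- comp$scale[k]
      delta <- comp$shape[k] / sqrt(1 + comp$shape[k]^2)
      Delta <- om * delta
      Gamma <- om^2 * (1 - delta^2)
      resid <- x - comp$location[k]
      s2 <- Gamma / (Gamma + Delta^2)
      m <- Delta * resid / (Gamma + Delta^2)
      s <- sqrt(s2)
      h <- exp(stats::dnorm(m / s, log = TRUE) -
                 stats::pnorm(m / s, log.p = TRUE))
      e1 <- m + s * h
      e2 <- m^2 + s2 + m * s * h
      w <- z[, k]
      sw <- sum(w)
      if (sw < .Machine$double.eps) next
      # CM-steps: xi | Delta, then Delta | xi, then Gamma
      xi <- sum(w * (x - Delta * e1)) / sw
      if (is.null(shape_fixed)) {
        Delta <- sum(w * (x - xi) * e1) / sum(w * e2)
      } else if (shape_fixed == 0) {
        Delta <- 0
      }
      rr <- x - xi
      Gamma <- sum(w * (rr^2 - 2 * Delta * rr * e1 + Delta^2 * e2)) / sw
      Gamma <- max(Gamma, scale_floor^2)
      om2 <- Gamma + Delta^2
      comp$location[k] <- xi
      comp$scale[k] <- sqrt(om2)
      comp$shape[k] <- if (is.null(shape_fixed))
        Delta / sqrt(Gamma) else shape_fixed
      comp$weight[k] <- sw / n
    }
    comp$weight <- comp$weight / sum(comp$weight)
    ld <- sn_mix_logdens(x, comp)
    ll_new <- sum(logsumexp_rows(ld))
    if (ll_new < ll - 1e-6 * max(1, abs(ll)))
      stopf("EM log-likelihood decreased (%.6g -> %.6g): internal error",
            ll, ll_new)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * max(1, abs(ll))) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(components = comp, loglik = ll, trace = trace, n_iter = it,
       converged = converged)
}

#' @export
print.sn_mixture <- function(x, ...) {
  cat(sprintf("skew-normal mixture, K = %d (n = %d, logLik = %.2f)\n",
              x$K, x$n, x$loglik))
  pct <- population_percentages(x)
  for (k in seq_len(nrow(x$components))) {
    c_ <- x$components[k, ]
    cat(sprintf("  %d: mean %.1f kDa (sd %.1f, shape %.2f), %d%%\n",
                k, c_$mean_kda, c_$sd_kda, c_$shape, pct[k]))
  }
  invisible(x)
}

#' Population percentages of a fitted mixture
#'
#' Component weights as whole-number percentages that sum exactly to 100,
#' reconciled by the largest-remainder rule (ties go to the later
#' component).
#'
#' @param model an [sn_mixture][fit_mixture()] (or numeric weight vector).
#' @return integer percentages summing to 100.
#' @examples
#' population_percentages(c(1, 1, 1) / 3)  # 33 33 34
#' @export
population_percentages <- function(model) {
  w <- if (inherits(model, "sn_mixture")) model$components$weight else model
  if (abs(sum(w) - 1) > 1e-6) stopf("weights must sum to 1")
  raw <- w * 100
  fl <- floor(raw)
  short <- 100L - as.integer(sum(fl))
  if (short > 0L) {
    rem <- raw - fl
    give <- order(rem, seq_along(rem), decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  }
  as.integer(fl)
}
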