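#' Labeling stoichiometry model
#'
#' Describes fluorescent labeling of an n-subunit complex in which each
#' subunit independently carries a dye with probability `p` (e.g. SNAP- or
#' ybbR-tag labeling of a homodimer). The chance that the complex is visible
#' at all is `1 - (1 - p)^n`.
#'
#' @param p per-monomer labeling probability, in `[0, 1]`.
#' @param n_subunits number of independently labeled subunits (>= 1).
#' @return an object of class `labeling_model`.
#' @seealso [labeling_probability()], [draw_dye_count()]
#' @export
labeling_model <- function(p, n_subunits = 2L) {
  assert_scalar_num(p, "p")
  if (p < 0 || p > 1) stopf("'p' must be in [0, 1]")
  assert_scalar_num(n_subunits, "n_subunits", positive = TRUE)
  structure(list(p = p, n_subunits = as.integer(n_subunits)),
            class = "labeling_model")
}

#' Probability that a labeled complex carries at least one dye
#'
#' For a complex of `n` subunits each labeled independently with probability
#' `p`, the probability of showing any signal is `1 - (1 - p)^n`. For a
#' homodimer this is the familiar `2p - p^2`.
#'
#' @param p per-monomer labeling probability, in `[0, 1]`. Vectorized.
#' @param n number of subunits (default 2, a homodimer).
#' @return probability (same length as `p`).
#' @examples
#' labeling_probability(0.65)        # SNAP-tag homodimer -> 0.8775
#' labeling_probability(0.50)        # ybbR-tag homodimer -> 0.75
#' @export
labeling_probability <- function(p, n = 2) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("'p' must be numeric in [0, 1]")
  assert_scalar_num(n, "n", positive = TRUE)
  1 - (1 - p)^n
}

#' At-least-one-dye probability for a homodimer
#'
#' Convenience form of [labeling_probability()] with `n = 2`, i.e.
#' `2p - p^2`.
#'
#' @inheritParams labeling_probability
#' @return probability.
#' @examples
#' dimer_labeling_probability(0.65)  # 0.8775, i.e. 0.88 at two decimals
#' @export
dimer_labeling_probability <- function(p) labeling_probability(p, n = 2)

#' Draw the number of dyes on complexes
#'
#' Binomial(n_subunits, p) draws, one per complex.
#'
#' @param label a [labeling_model()].
#' @param n_complexes how many complexes to draw for.
#' @return integer vector of dye counts in `0..n_subunits`.
#' @export
draw_dye_count <- function(label, n_complexes = 1L) {
  if (!inherits(label, "labeling_model")) stopf("'label' must be a labeling_model")
  stats::rbinom(n_complexes, size = label$n_subunits, prob = label$p)
}

#' Correct an observed colocalization fraction for incomplete labeling
#'
#' An observed bait-prey colocalized fraction underestimates the true bound
#' fraction when the prey is only visible with probability
#' `p_label_complex` (see [labeling_probability()]). The corrected estimate is
#' `observed / p_label_complex`, clipped to `[0, 1]` with a warning if the
#' division overshoots.
#'
#' @param observed_fraction observed fraction(s) in `[0, 1]`.
#' @param p_label_complex probability that a complex carries >= 1 dye, in
#'   `(0, 1]`.
#' @return corrected fraction(s).
#' @examples
#' correct_fraction_for_labeling(0.44, dimer_labeling_probability(0.65))
#' @export
correct_fraction_for_labeling <- function(observed_fraction, p_label_complex) {
  assert_scalar_num(p_label_complex, "p_label_complex")
  if (p_label_complex <= 0 || p_label_complex > 1)
    stopf("'p_label_complex' must be in (0, 1]")
  if (any(!is.finite(observed_fraction)) ||
      any(observed_fraction < 0 | observed_fraction > 1))
    stopf("'observed_fraction' must be in [0, 1]")
  corrected <- observed_fraction / p_label_complex
  if (any(corrected > 1)) {
    warnf("corrected fraction exceeds 1 (observed %g / p %g); clipping",
          max(observed_fraction), p_label_complex)
    corrected <- clamp01(corrected)
  }
  corrected
}
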