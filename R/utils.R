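# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  invisible(x)
}

#' @noRd
clamp01 <- function(x) pmin(1, pmax(0, x))

# robust noise scale: 1.4826 * median absolute deviation
#' @noRd
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
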