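#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed clonal percentages in this
#' field are conventionally rounded half-up (26/336 -> 7.738 -> 7.7), so a
#' dedicated helper is used everywhere a percentage is reported.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stream seed from a global seed
#'
#' One global integer seed drives a cohort; each sample gets its own stream
#' by a fixed jump offset so samples can be regenerated independently and
#' output is byte-identical under a fixed global seed.
#'
#' @param seed global integer seed
#' @param stream nonnegative integer stream index
#' @return integer seed below 2^31
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stopf("'%s' must be a single probability in [0, 1]", name)
  }
  invisible(x)
}
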