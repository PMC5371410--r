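# Internal helpers shared across modules.

# Classed conditions so callers and tests can distinguish failure modes
# without matching message text.
cr_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "cleaverate_error", "error", "condition")))
}

#' Round half away from zero
#'
#' Display rounding used in site reports: halves round away from zero
#' (899.5 -> 900), unlike base [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @examples
#' round_half_away(899.5)  # 900
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# decimal text that survives an exact numeric round trip
fmt_num <- function(x) {
  out <- character(length(x))
  whole <- is.finite(x) & x == floor(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out[!whole] <- sprintf("%.17g", x[!whole])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
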