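# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's round() rounds half to even; printed percentage tables in clinical
#' reports conventionally round half up, which is what the comparison tables
#' here use.
#' @param x numeric vector
#' @return integer-valued numeric
#' @keywords internal
halfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop unless a condition holds, with sprintf-style message.
stopifnot_msg <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Cohort z-score of a gene's expression row (mean 0, sd 1 across samples).
# A constant row has sd 0; its z-scores are defined as 0 so that downstream
# marker averaging stays finite.
rowZ <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mu) / s
}
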