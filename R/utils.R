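#' Round half away from zero
#'
#' Percentage reporting uses round-half-away-from-zero (so 25.45 -> 25.5,
#' -25.45 -> -25.5), unlike base [round()] which rounds half to even.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# spike counting convention: half-open window [from, to)
count_spikes <- function(times, from, to) {
  sum(times >= from & times < to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("aobtune_validation_error", "error", "condition")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("aobtune_format_error", "error", "condition")))
}

# full-precision numeric formatting so CSV round-trips are exact
fmt_num <- function(x) sprintf("%.17g", x)
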