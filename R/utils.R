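# Small shared helpers.

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Days in a calendar month (non-leap year)
#'
#' @param month Integer month 1-12.
#' @return Integer number of days.
#' @keywords internal
days_in_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  DAYS_IN_MONTH[month]
}

# Round half away from zero to `digits` decimals (commercial rounding, unlike
# base round()'s round-half-even). Used by the maize area estimation rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible child seed (kept below 2^31) from a base seed and an
# integer tag, so per-year random fields do not depend on which year range
# was requested.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
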