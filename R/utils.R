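# Internal helpers shared across modules.

# Round half away from zero (the convention used for reported percentages:
# 34.7 -> 35, 82.5 -> 83), unlike base round()'s banker's rounding.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Percentage on the 0-100 scale, rounded half-up.
as_pct <- function(p, digits = 0) round_half_up(100 * p, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
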