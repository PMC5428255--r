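# Internal numeric helpers.
#
# R's round() is round-half-even; segment boundary averages and imputed
# shifts need deterministic half-up / half-away-from-zero rounding so that
# e.g. the average of channels 14833 and 14839 is exactly 14836 and an
# imputed shift of -2.5 becomes -3, not -2.

round_half_up <- function(x) floor(x + 0.5)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Scaled median absolute deviation: 1.483 * median(|x - median(x)|).
# The 1.483 factor makes the estimate consistent with the standard
# deviation of a normal distribution.
mad_scaled <- function(x) 1.483 * stats::median(abs(x - stats::median(x)))

# 0-based channel slice of a signal vector (inclusive bounds).
ch_slice <- function(x, from, to) x[(from:to) + 1L]

stop_atsa <- function(...) stop(..., call. = FALSE)
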