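# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding; reported
# percentages follow the half-up convention used in the tables).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
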