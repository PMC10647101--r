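# Round half away from zero at `digits` decimals (commercial rounding).
# base::round() rounds half to even, which would report 9.95 -> 9.9 instead
# of the conventional 10.0 on percentage rows.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer with thousands separators, for the text cost table.
fmt_baht <- function(x) {
  formatC(x, format = "d", big.mark = ",", flag = "")
}

# Signed variant used on therapy-change rows.
fmt_baht_signed <- function(x) {
  ifelse(x > 0, paste0("+", fmt_baht(x)), fmt_baht(x))
}

`%||%` <- rlang::`%||%`
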