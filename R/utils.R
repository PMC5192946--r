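# Harmonic sums used throughout Watterson/Tajima/HKA arithmetic.
# a_n = sum_{i=1}^{n-1} 1/i ; b_n = sum_{i=1}^{n-1} 1/i^2
harmonic_a <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

harmonic_b <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
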