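# Internal helpers shared across modules.

# Round half away from zero for non-negative x (planted counts, extreme-set
# sizes). base::round() rounds half to even, which would make planted counts
# depend on parity.
round_half_up <- function(x) {
  floor(x + 0.5)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Benjamini-Hochberg step-up adjustment; NA p-values stay NA and do not
# count toward the family size.
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
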