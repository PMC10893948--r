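# shared internal helpers

# Round half away from zero at `digits` decimals. Printed per-plant rates in
# dose-response tables are half-up rounded (e.g. 1.205 -> 1.21), which differs
# from base round()'s round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_bad_arg("`%s` must be a single probability in [0, 1]", name)
  }
  invisible(x)
}

# Jaccard similarity of two half-open integer intervals [s1, e1) and [s2, e2)
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  ifelse(union > 0, inter / union, 0)
}
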