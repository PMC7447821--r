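# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Derive reproducible child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stopifnot with a readable classed error
check_that <- function(ok, msg, class = "clonefreq_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# format numbers for TSV output: 6 significant digits, no scientific notation
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "fg", flag = "#"))
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
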