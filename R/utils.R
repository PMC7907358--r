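# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish configuration, format,
# alignment, ... failures programmatically. `class` is the specific class;
# every condition also carries "refsig_error" / "refsig_warning".
stop_refsig <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "refsig_error")))
}

warn_refsig <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "refsig_warning")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package flows through
# this, so identical seeds give identical results regardless of call order.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed and a few small stream indices
# (run, classifier, fold, ...). Arithmetic in doubles, reduced mod a prime
# below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483629
  for (i in seq_along(idx)) {
    s <- (s * 69 + as.numeric(idx[i]) * c(1000003, 10007, 101, 13)[min(i, 4)]) %% 2147483629
  }
  as.integer(s)
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}
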