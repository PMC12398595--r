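# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lo = -Inf, hi = Inf,
                         integer = FALSE, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    abort_field(field, sprintf(
      "must lie in %s%s, %s%s (got %g)",
      if (open_lo) "(" else "[", format(lo), format(hi),
      if (open_hi) ")" else "]", x
    ))
  }
  if (integer && x != round(x)) abort_field(field, "must be an integer")
  if (integer) as.integer(x) else as.numeric(x)
}

check_matrix <- function(x, field) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort_field(field, "must be numeric")
  if (any(!is.finite(x))) abort_field(field, "contains non-finite values")
  x
}

# Deterministic fan-out of one user-facing seed into per-module streams.
# Kept below 2^31 - 1 so the result is a valid 32-bit integer seed.
derive_seed <- function(seed, stream) {
  seed <- as.double(seed)
  (abs(seed) * 48271 + 1000003 * as.double(stream)) %% 2147483629 + 1
}

# Probabilities are clamped before logs: the cross-entropy style losses are
# undefined at exactly 0/1.
PROB_EPS <- 1e-7

clamp_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

feature_cols <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

feature_matrix <- function(data) {
  cols <- feature_cols(data)
  if (length(cols) == 0L) {
    abort_field("data", "no feature columns f1..fd found")
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  m
}
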