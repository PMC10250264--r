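# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar checks used by constructors/validators
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  as.numeric(x)
}

check_count <- function(x, name, lower = 0L) {
  x <- check_number(x, name, lower = lower)
  if (x != round(x)) stopf("`%s` must be an integer, got %s", name, x)
  as.integer(x)
}

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a sub-seed for a named stage from a master seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
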