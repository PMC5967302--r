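# Internal validation helpers shared across modules.

# Scalar finite number check.
.is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_positive <- function(x, name) {
  if (!.is_num(x) || x <= 0) {
    stop(sprintf("`%s` must be a single finite number > 0 (got %s)",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!.is_num(x) || x < 0) {
    stop(sprintf("`%s` must be a single finite number >= 0 (got %s)",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!.is_num(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# All generators funnel their randomness through this single entry point.
.with_seed <- function(seed, expr) {
  .check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), expr)
}

# Lower median: for even n returns the lower of the two central order
# statistics, so medians of integer data stay integers.
.lower_median <- function(x) {
  n <- length(x)
  sort(x, partial = floor((n + 1) / 2))[floor((n + 1) / 2)]
}
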