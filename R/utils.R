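# internal helpers shared across modules

# run `expr` under a reproducible RNG state when `seed` is given; leave the
# global RNG untouched either way
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s (got %s).", name, format(min), format(x)))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s] (got %s).",
                  name, format(min), format(max), format(x)))
  }
  invisible(x)
}

check_column <- function(data, col, fn) {
  if (!col %in% names(data)) {
    abort(sprintf("`%s()` requires a `%s` column in `data`.", fn, col))
  }
  invisible(data[[col]])
}

# sample standard deviation that returns 0 (not NA) for length-1 input
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
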