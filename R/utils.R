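# internal helpers shared across modules

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          closedLower = TRUE, closedUpper = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  okLow <- if (closedLower) x >= lower else x > lower
  okUp <- if (closedUpper) x <= upper else x < upper
  if (!okLow || !okUp)
    stop("'", name, "' = ", x, " is outside the allowed range ",
         if (closedLower) "[" else "(", lower, ", ", upper,
         if (closedUpper) "]" else ")", call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, minimum = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x != round(x) || x < minimum)
    stop("'", name, "' must be an integer >= ", minimum, call. = FALSE)
  as.integer(x)
}

.assertSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L ||
      !is.numeric(seed) || !is.finite(seed) || seed != round(seed))
    stop("'seed' must be supplied as a single integer; ",
         "generators never rely on global RNG state", call. = FALSE)
  as.integer(seed)
}

# run expr under an explicit seed, leaving the caller's RNG state untouched
.withSeed <- function(seed, expr) {
  withr::with_seed(.assertSeed(seed), expr)
}

# standard error of the mean
.sem <- function(x) stats::sd(x) / sqrt(length(x))
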