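# Internal helpers shared across modules.

# Run `expr` under a locally seeded RNG stream, restoring the caller's
# .Random.seed afterwards so simulation helpers never perturb the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

stop_mutlab <- function(...) stop(..., call. = FALSE)

is_count_vector <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

# Round half away from zero, the convention of printed tables (base R's
# round() is round-half-even, which turns 6.25 into 6.2, not 6.3).
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Significant/decimal rounding convention used for printed relative rates:
# one decimal place below 100, three significant figures at or above 100.
round_relative <- function(x) {
  ifelse(abs(x) < 100, round_half_up(x, 1L), signif(x, 3L))
}

geometric_mean <- function(x) exp(mean(log(x)))
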