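# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Nearest-integer rounding, halves away from zero (unlike base round()'s
# round-half-even), the convention used when matching published percentages.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower || !strict_lower && x < lower) {
    stop_bad(sprintf("`%s` must be %s %g", name,
                     if (strict_lower) ">" else ">=", lower))
  }
  if (strict_upper && x >= upper || !strict_upper && x > upper) {
    stop_bad(sprintf("`%s` must be %s %g", name,
                     if (strict_upper) "<" else "<=", upper))
  }
  invisible(x)
}
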