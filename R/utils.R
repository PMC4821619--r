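.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard-normal quantile for a two-sided CI at level `ci_level`
# (1.959964 for the conventional 95%).
z_quantile <- function(ci_level = 0.95) {
  if (!is.numeric(ci_level) || any(ci_level <= 0) || any(ci_level >= 1))
    .stopf("`ci_level` must lie strictly between 0 and 1")
  qnorm(1 - (1 - ci_level) / 2)
}

# One unit in the last printed decimal of x: 1.06 -> 0.01, 1.3 -> 0.1.
# Used to tolerate rounding when checking ci_low <= estimate <= ci_high
# against values transcribed from printed tables.
.print_unit <- function(x) {
  s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, scientific = FALSE, trim = TRUE)))
  10^(-pmin(nchar(s), 6L))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
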