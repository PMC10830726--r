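# Shared internal helpers.

# round() in R is half-even; reported redundancy percentages follow the
# half-up convention used in printed summary tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Smallest multiple of `grid` strictly greater than `x`. Values within
# `tol` of a grid multiple are treated as sitting exactly on it, so the
# proposal still moves one full step up.
grid_round_up <- function(x, grid, tol = 1e-9) {
  stopifnot(is.numeric(x), length(x) == 1L, grid > 0)
  k <- floor(x / grid + tol) + 1L
  k * grid
}

`%sep%` <- function(ids, collapse = ", ") paste(ids, collapse = collapse)

# sample() treats a length-1 numeric x as 1:x; this does not
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}
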