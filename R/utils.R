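# Internal validation helpers shared across modules.

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Polyline arc length for an n x 2 coordinate matrix.
polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Resample an open polyline to n points equally spaced in arc length.
resample_polyline <- function(xy, n) {
  stopifnot(nrow(xy) >= 2L, n >= 2L)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- c(TRUE, seg > 0)          # drop zero-length segments for approx()
  s_u <- s[keep]
  target <- seq(0, total, length.out = n)
  cbind(
    approx(s_u, xy[keep, 1L], xout = target, rule = 2)$y,
    approx(s_u, xy[keep, 2L], xout = target, rule = 2)$y
  )
}

new_seed <- function(seed) {
  stop_if_not_count(seed, "seed", min = 0L)
  as.integer(seed %% .Machine$integer.max)
}
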