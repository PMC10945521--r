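# Independent oracles and small fixture builders used across the suite.

# Log-likelihood of a two-component zero-mean Gaussian mixture.
mixture_loglik <- function(x, f, s1, s2) {
  sum(log(f * dnorm(x, 0, s1) + (1 - f) * dnorm(x, 0, s2)))
}

# Dense grid search over (f, sigma_static, sigma_mobile) maximizing the
# mixture likelihood; the brute-force counterpart of the EM fit.
grid_search_mixture <- function(x, f_grid = seq(0.05, 0.95, by = 0.025),
                                s_lo = NULL, s_hi = NULL, n_s = 40L) {
  s_lo <- s_lo %||% (sd(x) / 10)
  s_hi <- s_hi %||% (sd(x) * 3)
  s_grid <- exp(seq(log(s_lo), log(s_hi), length.out = n_s))
  best <- list(ll = -Inf)
  for (f in f_grid) {
    for (i in seq_len(n_s)) {
      for (j in seq_len(n_s)) {
        if (s_grid[i] > s_grid[j]) next     # static sigma <= mobile sigma
        ll <- mixture_loglik(x, f, s_grid[i], s_grid[j])
        if (ll > best$ll) {
          best <- list(ll = ll, f = f, s_static = s_grid[i],
                       s_mobile = s_grid[j])
        }
      }
    }
  }
  best$s_step <- exp(diff(log(s_grid))[1L])  # multiplicative grid step
  best$f_step <- diff(f_grid)[1L]
  best
}

# Dense grid search minimizing the one-site binding SSE.
grid_search_one_site <- function(conc, resp,
                                 kd_range = c(0.5, 500),
                                 rmax_range = c(0.1, 5),
                                 n = 120L) {
  kd_grid <- exp(seq(log(kd_range[1L]), log(kd_range[2L]), length.out = n))
  rmax_grid <- seq(rmax_range[1L], rmax_range[2L], length.out = n)
  sse <- outer(kd_grid, rmax_grid, Vectorize(function(kd, rmax) {
    sum((resp - rmax * conc / (kd + conc))^2)
  }))
  i <- which(sse == min(sse), arr.ind = TRUE)[1L, ]
  list(kd = kd_grid[i[1L]], rmax = rmax_grid[i[2L]], sse = min(sse),
       kd_step = exp(diff(log(kd_grid))[1L]),
       rmax_step = diff(rmax_grid)[1L])
}

# Hand-built track set: one track per element of `frames`, with unit x step
# per frame and constant y.
toy_track_set <- function(frame_lists, dt = 0.03, step = 0.1) {
  rows <- purrr::imap(frame_lists, function(fr, i) {
    tibble::tibble(track_id = as.integer(i), frame = as.integer(fr),
                   x_um = step * seq_along(fr), y_um = 0)
  })
  track_set(dplyr::bind_rows(rows), frame_interval = dt)
}

# Rectangle mask with a margin, for straight-cell geometry checks.
rect_mask <- function(rows = 20, cols = 70, r = 6:15, c = 6:65) {
  m <- matrix(0L, rows, cols)
  m[r, c] <- 1L
  m
}
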