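#' Fit a two-population Gaussian mixture to pooled displacements
#'
#' Fits the frame-to-frame displacement model used to separate polymer-bound
#' ("static") from freely diffusing ("mobile") molecules: a two-component,
#' zero-mean Gaussian mixture over the pooled per-axis displacements, fitted
#' by expectation-maximization. For component i with standard deviation
#' sigma_i, the apparent diffusion coefficient is
#' D_i = sigma_i^2 / (2 * dt). Components are labelled so that
#' `d_static <= d_mobile`; ties are broken by weight (the heavier component
#' is called static).
#'
#' Reported D values are *apparent* (no localization-error deconvolution by
#' default; the sub-0.05 um^2/s static coefficient typically absorbs the
#' localization error). If the localization error SD is known, pass
#' `localization_sd` to subtract sigma_loc^2 / dt from both coefficients.
#'
#' @param ds A `displacement_sample` from [pooled_displacements()], or a
#'   numeric vector of displacements (then `frame_interval` must be given).
#' @param frame_interval Frame interval in seconds; taken from `ds` when it
#'   is a `displacement_sample`.
#' @param min_samples Minimum number of displacement samples (default 100).
#' @param fix_static_d Optional: fix the static component's diffusion
#'   coefficient (um^2/s) instead of fitting it.
#' @param localization_sd Known localization error SD (um) to subtract from
#'   the reported coefficients; default 0 (apparent D).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-9).
#' @param max_iter Iteration cap (default 1000).
#' @param bootstrap Number of bootstrap resamples for percentile confidence
#'   intervals (default 0 = none).
#'
#' @return A `mixture_fit` object with elements `f_static`, `d_static`,
#'   `d_mobile`, `sigma_static`, `sigma_mobile` (um), `log_likelihood`,
#'   `converged`, `degenerate`, `n_samples`, `n_iter`, `ll_trace`, and, with
#'   `bootstrap > 0`, a tibble `ci` of 95% percentile intervals.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
#' @examples
#' ts <- simulate_tracks(n_tracks = 200, f_static = 0.7, seed = 2)
#' fit <- fit_two_population(pooled_displacements(filter_tracks(ts)))
#' glance(fit)
fit_two_population <- function(ds,
                               frame_interval = NULL,
                               min_samples = 100L,
                               fix_static_d = NULL,
                               localization_sd = 0,
                               tol = 1e-9,
                               max_iter = 1000L,
                               bootstrap = 0L) {
  if (inherits(ds, "displacement_sample")) {
    x <- ds$displacement_um
    frame_interval <- frame_interval %||% attr(ds, "frame_interval")
  } else {
    x <- as.numeric(ds)
  }
  if (is.null(frame_interval)) {
    abort("`frame_interval` must be supplied for a plain numeric input")
  }
  stop_if_not_scalar_number(frame_interval, "frame_interval", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(localization_sd, "localization_sd", 0)
  min_samples <- stop_if_not_count(min_samples, "min_samples")
  if (length(x) < min_samples) {
    abort(sprintf("need >= %d displacement samples, got %d",
                  min_samples, length(x)))
  }

  dt <- frame_interval
  fix_sigma <- if (!is.null(fix_static_d)) {
    stop_if_not_scalar_number(fix_static_d, "fix_static_d", 0)
    sqrt(2 * fix_static_d * dt)
  }

  em <- em_zero_mean_mixture(x, tol = tol, max_iter = max_iter,
                             fix_sigma1 = fix_sigma)

  fit <- label_mixture(em, dt, localization_sd)
  fit$n_samples <- length(x)
  fit$frame_interval <- dt
  fit$samples <- x

  if (bootstrap > 0L) {
    bootstrap <- stop_if_not_count(bootstrap, "bootstrap")
    reps <- map(seq_len(bootstrap), function(b) {
      xb <- sample(x, replace = TRUE)
      eb <- em_zero_mean_mixture(xb, tol = tol, max_iter = max_iter,
                                 fix_sigma1 = fix_sigma)
      lb <- label_mixture(eb, dt, localization_sd)
      c(f_static = lb$f_static, d_static = lb$d_static,
        d_mobile = lb$d_mobile)
    })
    bm <- do.call(rbind, reps)
    fit$ci <- tibble(
      term = colnames(bm),
      lower = apply(bm, 2L, quantile, 0.025),
      upper = apply(bm, 2L, quantile, 0.975)
    )
  }
  structure(fit, class = "mixture_fit")
}

# EM for a two-component zero-mean Gaussian mixture on scalar samples.
# Deterministic initialization: sigma estimates from the 25th and 90th
# percentiles of |x| (scale-free), equal weights. Component 1 is the
# narrower starting component; optionally its sigma is held fixed.
em_zero_mean_mixture <- function(x, tol = 1e-9, max_iter = 1000L,
                                 fix_sigma1 = NULL) {
  n <- length(x)
  ax <- abs(x)
  if (all(ax < .Machine$double.eps^0.5)) {
    return(list(w = c(1, 0), sigma = c(0, 0), loglik = NA_real_,
                converged = TRUE, degenerate = TRUE, n_iter = 0L,
                ll_trace = numeric(0)))
  }
  # |x| ~ half-normal: sd = quantile / qnorm((1+p)/2)
  s1 <- fix_sigma1 %||% (quantile(ax, 0.25, names = FALSE) / qnorm(0.625))
  s2 <- quantile(ax, 0.90, names = FALSE) / qnorm(0.95)
  s_floor <- max(1e-8, 1e-6 * sd(x))
  s1 <- max(s1, s_floor); s2 <- max(s2, s_floor)
  if (abs(s1 - s2) < s_floor) s2 <- s1 * 2   # ensure distinct start
  w <- 0.5

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  x2 <- x^2
  for (iter in seq_len(max_iter)) {
    p1 <- w * dnorm(x, 0, s1)
    p2 <- (1 - w) * dnorm(x, 0, s2)
    tot <- p1 + p2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- p1 / tot
    sg <- sum(g)
    w <- sg / n
    if (is.null(fix_sigma1)) {
      s1 <- max(sqrt(sum(g * x2) / max(sg, 1e-300)), s_floor)
    }
    s2 <- max(sqrt(sum((1 - g) * x2) / max(n - sg, 1e-300)), s_floor)
  }
  list(w = c(w, 1 - w), sigma = c(s1, s2), loglik = ll_trace[length(ll_trace)],
       converged = converged, degenerate = FALSE, n_iter = iter,
       ll_trace = ll_trace)
}

label_mixture <- function(em, dt, localization_sd = 0) {
  if (em$degenerate) {
    return(list(f_static = 1, d_static = 0, d_mobile = 0,
                sigma_static = 0, sigma_mobile = 0,
                log_likelihood = em$loglik, converged = em$converged,
                degenerate = TRUE, n_iter = em$n_iter,
                ll_trace = em$ll_trace))
  }
  # smaller sigma = static; near-tie broken by weight (heavier = static)
  if (isTRUE(all.equal(em$sigma[1L], em$sigma[2L], tolerance = 1e-6))) {
    static_i <- which.max(em$w)
  } else {
    static_i <- which.min(em$sigma)
  }
  mobile_i <- 3L - static_i
  d_corr <- localization_sd^2 / dt
  near_degenerate <- min(em$w) < 0.005 ||
    isTRUE(all.equal(em$sigma[1L], em$sigma[2L], tolerance = 1e-3))
  list(
    f_static = em$w[static_i],
    d_static = max(em$sigma[static_i]^2 / (2 * dt) - d_corr, 0),
    d_mobile = max(em$sigma[mobile_i]^2 / (2 * dt) - d_corr, 0),
    sigma_static = em$sigma[static_i],
    sigma_mobile = em$sigma[mobile_i],
    log_likelihood = em$loglik,
    converged = em$converged,
    degenerate = near_degenerate,
    n_iter = em$n_iter,
    ll_trace = em$ll_trace
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-population displacement mixture fit\n")
  cat(sprintf("  static: f = %.3f, D = %.4f um^2/s\n", x$f_static,
              x$d_static))
  cat(sprintf("  mobile: f = %.3f, D = %.4f um^2/s\n", 1 - x$f_static,
              x$d_mobile))
  cat(sprintf("  logLik = %.2f | n = %d | %s%s\n", x$log_likelihood,
              x$n_samples,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) " (near-degenerate)" else ""))
  invisible(x)
}

#' @rdname fit_two_population
#' @param x A `mixture_fit`.
#' @param ... Ignored.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  out <- tibble(
    component = c("static", "mobile"),
    fraction = c(x$f_static, 1 - x$f_static),
    diffusion_um2_s = c(x$d_static, x$d_mobile),
    sigma_um = c(x$sigma_static, x$sigma_mobile)
  )
  if (!is.null(x$ci)) {
    ci <- x$ci
    out$fraction_low <- c(ci$lower[ci$term == "f_static"], NA)
    out$fraction_high <- c(ci$upper[ci$term == "f_static"], NA)
    out$diffusion_low <- c(ci$lower[ci$term == "d_static"],
                           ci$lower[ci$term == "d_mobile"])
    out$diffusion_high <- c(ci$upper[ci$term == "d_static"],
                            ci$upper[ci$term == "d_mobile"])
  }
  out
}

#' @rdname fit_two_population
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    f_static = x$f_static,
    d_static = x$d_static,
    d_mobile = x$d_mobile,
    log_likelihood = x$log_likelihood,
    n_samples = x$n_samples,
    n_iter = x$n_iter,
    converged = x$converged,
    degenerate = x$degenerate
  )
}

#' @rdname fit_two_population
#' @param object A `mixture_fit`.
#' @param bins Histogram bin count for `autoplot`.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, bins = 80, ...) {
  df <- tibble(displacement_um = object$samples)
  rng <- range(df$displacement_um)
  grid <- seq(rng[1L], rng[2L], length.out = 400)
  dens <- tibble(
    displacement_um = rep(grid, 3L),
    density = c(
      object$f_static * dnorm(grid, 0, max(object$sigma_static, 1e-12)),
      (1 - object$f_static) * dnorm(grid, 0, object$sigma_mobile),
      object$f_static * dnorm(grid, 0, max(object$sigma_static, 1e-12)) +
        (1 - object$f_static) * dnorm(grid, 0, object$sigma_mobile)
    ),
    component = rep(c("static", "mobile", "mixture"), each = length(grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$displacement_um)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "frame-to-frame displacement (µm)", y = "density")
}
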