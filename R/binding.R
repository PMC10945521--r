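#' Simulate steady-state one-site binding responses
#'
#' Generates the concentration/response series of a bio-layer
#' interferometry steady-state experiment from the one-site (hyperbolic)
#' model R(C) = Rmax * C / (KD + C), plus Gaussian noise.
#'
#' @param kd Equilibrium dissociation constant, uM (> 0).
#' @param rmax Maximal response, nm wavelength shift (> 0).
#' @param concentrations Analyte concentrations, uM (strictly positive).
#' @param noise_sd Gaussian noise SD in nm (default 0).
#' @param seed Integer seed.
#' @return A `binding_series` tibble: `concentration_uM`, `response_nm`,
#'   with the generating parameters as a `truth` attribute.
#' @export
#' @examples
#' simulate_binding(kd = 15, rmax = 1.2,
#'                  concentrations = c(1.875, 3.75, 7.5, 15, 30, 60, 120, 240))
simulate_binding <- function(kd = 15,
                             rmax = 1.2,
                             concentrations = c(1.875, 3.75, 7.5, 15, 30,
                                                60, 120, 240),
                             noise_sd = 0,
                             seed = 1L) {
  stop_if_not_scalar_number(kd, "kd", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(rmax, "rmax", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  if (any(concentrations <= 0)) abort("concentrations must be > 0")
  set.seed(new_seed(seed))
  r <- rmax * concentrations / (kd + concentrations)
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  out <- tibble(concentration_uM = as.numeric(concentrations),
                response_nm = r)
  attr(out, "truth") <- list(kd = kd, rmax = rmax, noise_sd = noise_sd)
  class(out) <- c("binding_series", class(out))
  out
}

#' Fit the one-site binding model to steady-state responses
#'
#' Least-squares fit of R(C) = Rmax * C / (KD + C) to maximal wavelength
#' shifts plotted against analyte concentration, the standard analysis of a
#' BLI steady-state series. Initialization is deterministic (KD0 = median
#' concentration, Rmax0 = max response); both parameters are constrained
#' positive. A reference-sensor column, when present, is subtracted
#' point-wise before fitting.
#'
#' @param data A data frame with columns `concentration_uM`, `response_nm`
#'   and optionally `control_nm` (reference sensor, subtracted).
#' @return A `binding_fit`: `kd` (uM), `rmax` (nm), standard errors,
#'   `residual_norm` (nm), the underlying `nls` fit and the fitted data.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
#' @examples
#' fit <- fit_one_site(simulate_binding(kd = 15, rmax = 1.2))
#' glance(fit)
fit_one_site <- function(data) {
  require_columns(data, c("concentration_uM", "response_nm"),
                  "binding series")
  df <- as_tibble(data)
  if ("control_nm" %in% names(df)) {
    df$response_nm <- df$response_nm - df$control_nm
  }
  if (any(df$concentration_uM <= 0)) abort("concentrations must be > 0")
  if (dplyr::n_distinct(df$concentration_uM) < 3L) {
    abort("need responses at >= 3 distinct concentrations")
  }
  if (max(abs(df$response_nm)) < 1e-12 ||
      max(df$response_nm) <= 0) {
    abort("no specific binding: responses are ~0 after control subtraction")
  }

  # KD start: concentration nearest the half-maximal response (falls back
  # to the median concentration when the series does not bracket half-max)
  half <- max(df$response_nm) / 2
  kd0 <- df$concentration_uM[which.min(abs(df$response_nm - half))]
  if (kd0 <= 0 || !is.finite(kd0)) kd0 <- median(df$concentration_uM)
  start <- list(kd = kd0, rmax = max(df$response_nm))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_nm ~ rmax * concentration_uM / (kd + concentration_uM),
      data = df, start = start,
      lower = c(kd = 1e-12, rmax = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
    ),
    error = function(e) abort(paste0("one-site fit failed to converge: ",
                                     conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, rmax = NA_real_))
  structure(list(
    kd = unname(est["kd"]),
    rmax = unname(est["rmax"]),
    kd_se = unname(se["kd"]),
    rmax_se = unname(se["rmax"]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    fit = fit,
    data = df
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "One-site binding fit: KD = %.3g uM (SE %.2g), Rmax = %.3g nm (SE %.2g)\n",
    x$kd, x$kd_se, x$rmax, x$rmax_se))
  invisible(x)
}

#' @rdname fit_one_site
#' @param x,object A `binding_fit`.
#' @param ... Ignored.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("kd", "rmax"),
         estimate = c(x$kd, x$rmax),
         std.error = c(x$kd_se, x$rmax_se),
         unit = c("uM", "nm"))
}

#' @rdname fit_one_site
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, rmax = x$rmax, residual_norm = x$residual_norm,
         n = nrow(x$data))
}

#' @rdname fit_one_site
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  rng <- range(object$data$concentration_uM)
  grid <- tibble(concentration_uM = exp(seq(log(rng[1L]), log(rng[2L]),
                                            length.out = 200)))
  grid$response_nm <- object$rmax * grid$concentration_uM /
    (object$kd + grid$concentration_uM)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_uM, .data$response_nm)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (µM)", y = "maximal shift (nm)")
}

#' Simulate a 1:1 binding kinetic trace
#'
#' Closed-form association/dissociation curves of the standard 1:1 BLI
#' model: association R(t) = Req * (1 - exp(-(kon*C + koff) * t)) with
#' Req = Rmax * C / (KD + C) and KD = koff/kon; dissociation
#' R(t) = R0 * exp(-koff * t).
#'
#' @param k_on Association rate, 1/(uM s).
#' @param k_off Dissociation rate, 1/s.
#' @param concentration Analyte concentration, uM.
#' @param rmax Maximal response, nm.
#' @param times Time points, s.
#' @param phase `"association"` or `"dissociation"`.
#' @param r0 Response at the start of dissociation (defaults to the
#'   association plateau Req).
#' @return A tibble `time_s`, `response_nm` with a `params` attribute.
#' @export
simulate_kinetic_trace <- function(k_on, k_off, concentration, rmax, times,
                                   phase = c("association", "dissociation"),
                                   r0 = NULL) {
  phase <- match.arg(phase)
  stop_if_not_scalar_number(k_on, "k_on", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(k_off, "k_off", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(concentration, "concentration", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(rmax, "rmax", 0, strict_lower = TRUE)
  kd <- k_off / k_on
  req <- rmax * concentration / (kd + concentration)
  r <- if (phase == "association") {
    req * (1 - exp(-(k_on * concentration + k_off) * times))
  } else {
    (r0 %||% req) * exp(-k_off * times)
  }
  out <- tibble(time_s = as.numeric(times), response_nm = r)
  attr(out, "params") <- list(k_on = k_on, k_off = k_off, kd = kd,
                              req = req, phase = phase)
  out
}

#' Simulate an exponential growth curve
#'
#' OD(t) = od0 * exp(mu * t) plus Gaussian noise; the substrate for
#' doubling-time estimation from plate-reader data.
#'
#' @param mu Exponential growth rate, 1/h.
#' @param od0 Initial optical density (> 0).
#' @param times Time points, h.
#' @param noise_sd Gaussian noise SD on OD (default 0).
#' @param seed Integer seed.
#' @return A tibble `time_h`, `od`.
#' @export
simulate_growth <- function(mu, od0 = 0.02,
                            times = seq(0, 12, by = 1 / 3),
                            noise_sd = 0, seed = 1L) {
  stop_if_not_scalar_number(mu, "mu")
  stop_if_not_scalar_number(od0, "od0", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  set.seed(new_seed(seed))
  od <- od0 * exp(mu * times)
  if (noise_sd > 0) od <- pmax(od + rnorm(length(od), 0, noise_sd), 1e-6)
  tibble(time_h = as.numeric(times), od = od)
}

#' Fit an exponential growth rate and doubling time
#'
#' Least-squares line through ln(OD) versus time within the stated window:
#' the slope is the exponential growth rate mu (1/h) and the doubling time
#' is t_d = ln(2)/mu. A non-positive mu leaves t_d undefined (NA, flagged).
#'
#' @param curve A data frame `time_h`, `od` (strictly increasing times,
#'   positive OD).
#' @param window `c(t_start, t_end)` in hours; defaults to the full range.
#'   See [suggest_growth_window()] for a data-driven choice.
#' @return A `growth_fit`: `mu` (1/h), `t_d` (h), `window`, `r2`,
#'   `t_d_defined`, `n_points`. `tidy()`/`glance()` provided.
#' @export
#' @examples
#' g <- fit_growth(simulate_growth(mu = log(2) / 2))
#' g$t_d   # 2 h
fit_growth <- function(curve, window = NULL) {
  require_columns(curve, c("time_h", "od"), "growth curve")
  df <- as_tibble(curve)
  if (any(diff(df$time_h) <= 0)) abort("times must be strictly increasing")
  if (any(df$od <= 0)) abort("OD values must be > 0")
  window <- window %||% range(df$time_h)
  sel <- df$time_h >= window[1L] & df$time_h <= window[2L]
  if (sum(sel) < 3L) abort("need >= 3 points inside the window")
  m <- lm(log(od) ~ time_h, data = df[sel, ])
  mu <- unname(coef(m)[2L])
  r2 <- suppressWarnings(summary(m)$r.squared)   # exact fits warn in summary
  defined <- mu > 1e-12                # a ~1e-17 slope on flat data is zero
  if (!defined) {
    warn("fitted growth rate is not positive; doubling time undefined")
  }
  structure(list(
    mu = mu,
    t_d = if (defined) log(2) / mu else NA_real_,
    t_d_defined = defined,
    window = as.numeric(window),
    r2 = r2,
    n_points = sum(sel),
    fit = m
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth fit: mu = %.4g 1/h, t_d = %s h (window %.2f-%.2f h, R2 = %.4f)\n",
    x$mu, if (x$t_d_defined) sprintf("%.3g", x$t_d) else "undefined",
    x$window[1L], x$window[2L], x$r2))
  invisible(x)
}

#' @rdname fit_growth
#' @param x A `growth_fit`.
#' @param ... Ignored.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("mu", "t_d"),
         estimate = c(x$mu, x$t_d),
         unit = c("1/h", "h"))
}

#' @rdname fit_growth
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(mu = x$mu, t_d = x$t_d, r2 = x$r2, n_points = x$n_points,
         window_start = x$window[1L], window_end = x$window[2L])
}

#' Suggest the exponential-phase window for a growth fit
#'
#' Slides a window of `span_points` consecutive measurements along the
#' curve and returns the window whose log-linear fit has the highest R^2 —
#' a data-driven stand-in for a hand-picked exponential phase.
#'
#' @param curve A data frame `time_h`, `od`.
#' @param span_points Window size in measurements (default 10).
#' @return `c(t_start, t_end)` in hours.
#' @export
suggest_growth_window <- function(curve, span_points = 10L) {
  require_columns(curve, c("time_h", "od"), "growth curve")
  span_points <- stop_if_not_count(span_points, "span_points", min = 3L)
  df <- as_tibble(curve)
  n <- nrow(df)
  if (n < span_points) abort("curve shorter than `span_points`")
  best <- c(-Inf, 1L)
  for (i in seq_len(n - span_points + 1L)) {
    sl <- i:(i + span_points - 1L)
    m <- lm(log(od) ~ time_h, data = df[sl, ])
    r2 <- suppressWarnings(summary(m)$r.squared)
    if (coef(m)[2L] > 0 && r2 > best[1L]) best <- c(r2, i)
  }
  i <- best[2L]
  c(df$time_h[i], df$time_h[i + span_points - 1L])
}
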