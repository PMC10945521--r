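test_that("the simulated hyperbola obeys its closed-form identities", {
  # half-saturation at C = KD
  bs <- simulate_binding(kd = 15, rmax = 1.2, concentrations = 15,
                         noise_sd = 0)
  expect_equal(bs$response_nm, 0.6)
  # saturation limit
  bs2 <- simulate_binding(kd = 15, rmax = 1.2, concentrations = 15000,
                          noise_sd = 0)
  expect_equal(bs2$response_nm, 1.2, tolerance = 1e-3)
  # strict monotonicity over the standard ladder
  bs3 <- simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0)
  expect_length(bs3$response_nm, 8L)
  expect_true(all(diff(bs3$response_nm) > 0))
  expect_error(simulate_binding(concentrations = c(-1, 5)), "> 0")
  expect_error(simulate_binding(kd = 0), "kd")
})

test_that("noiseless one-site data is recovered to solver precision", {
  bs <- simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0)
  fit <- fit_one_site(bs)
  expect_equal(fit$kd, 15, tolerance = 1e-6)
  expect_equal(fit$rmax, 1.2, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("three points constructed from the hyperbola pin the fit", {
  kd <- 8; rmax <- 2
  conc <- c(kd, 800, 1600)                   # half-saturation + 2 saturating
  resp <- rmax * conc / (kd + conc)
  fit <- fit_one_site(tibble::tibble(concentration_uM = conc,
                                     response_nm = resp))
  expect_equal(fit$kd, kd, tolerance = 1e-5)
  expect_equal(fit$rmax, rmax, tolerance = 1e-5)
})

test_that("2% response noise still localizes KD within 15%", {
  bs <- simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0.02 * 1.2,
                         seed = 33)
  fit <- fit_one_site(bs)
  expect_equal(fit$kd, 15, tolerance = 0.15)
})

test_that("the least-squares optimum matches a dense grid search", {
  conc <- c(2, 8, 30, 120, 240)
  set.seed(3)
  resp <- 1.1 * conc / (20 + conc) + rnorm(5, 0, 0.02)
  fit <- fit_one_site(tibble::tibble(concentration_uM = conc,
                                     response_nm = resp))
  oracle <- grid_search_one_site(conc, resp)
  expect_lte(fit$residual_norm^2, oracle$sse + 1e-10)
  expect_equal(fit$kd, oracle$kd, tolerance = 2 * (oracle$kd_step - 1))
  expect_equal(fit$rmax, oracle$rmax, tolerance = 2 * oracle$rmax_step)
})

test_that("the fitted curve is monotone and concave over the sampled range", {
  bs <- simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0.03, seed = 2)
  fit <- fit_one_site(bs)
  grid <- seq(min(bs$concentration_uM), max(bs$concentration_uM),
              length.out = 100)
  r <- fit$rmax * grid / (fit$kd + grid)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(diff(r)) < 1e-12))
})

test_that("control responses are subtracted and flat data is refused", {
  bs <- simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0)
  with_ctrl <- dplyr::mutate(tibble::as_tibble(bs),
                             response_nm = response_nm + 0.2,
                             control_nm = 0.2)
  fit <- fit_one_site(with_ctrl)
  expect_equal(fit$kd, 15, tolerance = 1e-6)

  flat <- tibble::tibble(concentration_uM = c(1, 10, 100),
                         response_nm = c(0, 0, 0))
  expect_error(fit_one_site(flat), "no specific binding")
  expect_error(fit_one_site(bs[1:2, ]), "distinct concentrations")
})

test_that("kinetic traces follow the 1:1 closed forms", {
  k_on <- 0.01; k_off <- 0.15; conc <- 30; rmax <- 1.2
  kd <- k_off / k_on
  req <- rmax * conc / (kd + conc)
  assoc <- simulate_kinetic_trace(k_on, k_off, conc, rmax,
                                  times = seq(0, 300, 0.5))
  expect_equal(assoc$response_nm[nrow(assoc)], req, tolerance = 1e-6)
  dis <- simulate_kinetic_trace(k_on, k_off, conc, rmax,
                                times = log(2) / k_off, phase = "dissociation")
  expect_equal(dis$response_nm, req / 2)     # half-life = ln2/k_off
})

test_that("steady-state plateaus across a ladder recover KD = k_off/k_on", {
  k_on <- 0.02; k_off <- 0.3                 # KD = 15 uM
  conc <- c(1.875, 3.75, 7.5, 15, 30, 60, 120, 240)
  plateau <- vapply(conc, function(C) {
    tr <- simulate_kinetic_trace(k_on, k_off, C, rmax = 1.2, times = 1000)
    tr$response_nm
  }, numeric(1))
  fit <- fit_one_site(tibble::tibble(concentration_uM = conc,
                                     response_nm = plateau))
  expect_equal(fit$kd, k_off / k_on, tolerance = 1e-4)
})

test_that("growth curves and fits obey t_d = ln(2)/mu", {
  # one doubling in 2 h
  gc <- simulate_growth(mu = log(2) / 2, od0 = 0.02, times = c(0, 1, 2),
                        noise_sd = 0)
  expect_equal(gc$od[3], 0.04)
  fit <- fit_growth(gc)
  expect_equal(fit$t_d, 2)
  expect_identical(fit$t_d * fit$mu, log(2))  # exact by construction

  # flat curve: mu = 0, t_d undefined and flagged
  flat <- tibble::tibble(time_h = 0:5, od = rep(0.05, 6))
  expect_warning(f0 <- fit_growth(flat), "not positive")
  expect_true(is.na(f0$t_d))
  expect_false(f0$t_d_defined)
})

test_that("noisy growth round-trips within 5% and windows help", {
  gc <- simulate_growth(mu = 0.5, od0 = 0.02, times = seq(0, 8, by = 1 / 3),
                        noise_sd = 0.01 * 0.02, seed = 5)
  fit <- fit_growth(gc, window = c(0, 8))
  expect_equal(fit$mu, 0.5, tolerance = 0.05)
  # regenerating the curve from the fit matches the input
  regen <- simulate_growth(mu = fit$mu, od0 = 0.02,
                           times = gc$time_h, noise_sd = 0)
  expect_equal(log(regen$od), log(gc$od), tolerance = 0.05)

  # window suggestion finds the exponential phase of a saturating curve
  times <- seq(0, 16, by = 0.25)
  od <- 0.5 / (1 + exp(-0.6 * (times - 8)))  # logistic
  win <- suggest_growth_window(tibble::tibble(time_h = times, od = od),
                               span_points = 12)
  expect_lte(win[2], 8)                      # before the logistic inflection
  expect_equal(diff(win), 11 * 0.25)
})

test_that("growth input validation is strict", {
  expect_error(fit_growth(tibble::tibble(time_h = c(0, 1, 1), od = 1:3)),
               "increasing")
  expect_error(fit_growth(tibble::tibble(time_h = 0:2, od = c(1, -1, 1))),
               "> 0")
  expect_error(simulate_growth(mu = 0.5, od0 = 0), "od0")
})
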