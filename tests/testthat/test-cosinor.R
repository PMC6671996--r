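test_that("noiseless sinusoid parameters are recovered exactly", {
  t <- seq(0, 47, by = 1)
  y <- 5 + 2 * cos(2 * pi * (t - 20) / 24)
  fit <- fit_cosinor(t, y)
  expect_equal(fit$mesor, 5, tolerance = 1e-12)
  expect_equal(fit$amplitude, 2, tolerance = 1e-12)
  expect_equal(fit$acrophase, 20, tolerance = 1e-10)
  # refitting the fit's own curve reproduces it
  fit2 <- fit_cosinor(t, predict(fit, t))
  expect_equal(fit2$mesor, fit$mesor)
  expect_equal(fit2$amplitude, fit$amplitude, tolerance = 1e-12)
  expect_equal(fit2$acrophase, fit$acrophase, tolerance = 1e-10)
})

test_that("constant series yields zero amplitude and normalized phase", {
  fit <- fit_cosinor(seq(0, 30), rep(7, 31))
  expect_equal(fit$mesor, 7)
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_true(fit$acrophase >= 0 && fit$acrophase < 24)
})

test_that("degenerate sampling designs are rejected", {
  expect_error(fit_cosinor(c(0, 24, 48, 72), c(1, 1, 1, 1)), "degenerate")
  expect_error(fit_cosinor(0:2, 1:3), "4 samples")
  expect_error(fit_cosinor(c(0, 5, 10, 15), c(1, 2, 1, 2)), "span")
})

test_that("time-shifting the data shifts only the acrophase", {
  t <- seq(0, 72, by = 0.5)
  y <- 3 + 1.5 * cos(2 * pi * (t - 8) / 24) + sin(t)  # non-cosine remainder
  f0 <- fit_cosinor(t, y)
  f3 <- fit_cosinor(t + 3, y)
  expect_equal(f3$mesor, f0$mesor, tolerance = 1e-8)
  expect_equal(f3$amplitude, f0$amplitude, tolerance = 1e-8)
  expect_equal((f3$acrophase - f0$acrophase) %% 24, 3, tolerance = 1e-6)
})

test_that("noisy recovery stays within parametric standard errors", {
  set.seed(42)
  t <- seq(0, 240 - 1, by = 1)
  hits <- replicate(200, {
    y <- 5 + 2 * cos(2 * pi * (t - 20) / 24) + rnorm(length(t), 0, 0.1)
    fit <- fit_cosinor(t, y)
    c(abs(fit$mesor - 5) <= 3 * fit$se["mesor"],
      abs(fit$amplitude - 2) <= 3 * fit$se["amplitude"],
      hpaclock:::circular_diff(fit$acrophase, 20) <=
        3 * fit$se["acrophase"])
  })
  expect_gte(mean(hits), 0.99)
})

test_that("calibration acceptance is a per-parameter 1 SD box with wrap", {
  tgt <- calibration_target(5, 2, 0.1, sd_mesor = 0.5, sd_amplitude = 0.2,
                            sd_acrophase = 0.5)
  exact <- list(mesor = 5, amplitude = 2, acrophase = 0.1)
  expect_true(passes_calibration(exact, tgt))
  # circular wraparound across midnight
  expect_true(passes_calibration(list(mesor = 5, amplitude = 2,
                                      acrophase = 23.9), tgt))
  # single-criterion failure: amplitude off by 2 SD
  expect_false(passes_calibration(list(mesor = 5, amplitude = 2.4,
                                       acrophase = 0.1), tgt))
  # acceptance is monotone under shrinking deviations
  devs <- seq(0, 1.5, by = 0.25)
  pass <- vapply(devs, function(d)
    passes_calibration(list(mesor = 5 + d * 0.5, amplitude = 2,
                            acrophase = 0.1), tgt), logical(1))
  expect_true(all(diff(as.integer(pass)) <= 0))
})

test_that("the optional RMSE criterion tightens acceptance", {
  tgt <- calibration_target(5, 2, 12, sd_mesor = 1, sd_amplitude = 1,
                            sd_acrophase = 2)
  near <- list(mesor = 5.5, amplitude = 2.5, acrophase = 13)
  expect_true(passes_calibration(near, tgt))
  expect_false(passes_calibration(near, tgt, rmse_tol = 0.1))
  expect_true(passes_calibration(list(mesor = 5, amplitude = 2,
                                      acrophase = 12), tgt,
                                 rmse_tol = 0.1))
})

test_that("calibration targets round-trip through YAML", {
  tgt <- calibration_target(1.6, 2.7, 11.5, 0.16, 0.27, 1)
  path <- tempfile(fileext = ".yaml")
  write_calibration_target(tgt, path)
  tgt2 <- read_calibration_target(path)
  expect_equal(tgt2$mesor, tgt$mesor)
  expect_equal(tgt2$sd, tgt$sd)
  unlink(path)
})
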