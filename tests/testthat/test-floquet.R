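test_that("generic monodromy reproduces the Stuart-Landau spectrum", {
  lambda <- 1; omega <- 2
  period <- 2 * pi / omega
  M <- monodromy_matrix(sl_f(lambda, omega), sl_jac(lambda, omega),
                        y0 = c(1, 0), period = period)
  mult <- sort(Mod(eigen(M, only.values = TRUE)$values))
  # trivial multiplier 1; nontrivial exponent exactly -2 lambda
  expect_equal(mult[2], 1, tolerance = 1e-8)
  expect_equal(log(mult[1]) / period, -2 * lambda, tolerance = 1e-6)
})

test_that("the entrained HPA orbit is linearly stable", {
  fr <- floquet_exponents(default_parameters(), light_schedule(),
                          transient_days = 15, tol = 1e-5, rtol = 1e-9,
                          atol = 1e-11)
  expect_true(all(Mod(fr$multipliers) < 1))
  expect_lt(fr$leading_exponent, 0)
  expect_true(is.na(fr$trivial_multiplier))
  expect_equal(fr$period, 24)
})

test_that("the free-running orbit carries a unit trivial multiplier", {
  fr <- floquet_exponents(default_parameters(), constant_darkness(),
                          transient_days = 40, tol = 1e-6)
  expect_equal(Mod(fr$trivial_multiplier), 1, tolerance = 1e-6)
  expect_lt(fr$leading_exponent, 0)
  expect_gt(fr$period, 24)   # free-running period exceeds 24 h here
})

test_that("the Floquet exponent predicts the observed relaxation rate", {
  # perturb the converged entrained orbit and fit the decay of the CORT
  # peak deviation over successive cycles
  p <- default_parameters()
  fr <- floquet_exponents(p, light_schedule(), transient_days = 15,
                          tol = 1e-5, rtol = 1e-9, atol = 1e-11)
  cyc <- integrate_to_limit_cycle(p, light_schedule(),
                                  transient_days = 15, tol = 1e-5,
                                  dt = 0.05, rtol = 1e-9, atol = 1e-11)
  y0 <- cyc$states[1, ]
  ypert <- y0 * (1 + c(rep(0, 7), rep(0.15, 7)))  # hormonal perturbation
  tr <- integrate_hpa(p, light_schedule(), cyc$times[1],
                      cyc$times[1] + 12 * 24, dt = 0.05, y0 = ypert,
                      rtol = 1e-9, atol = 1e-11)
  ref <- integrate_hpa(p, light_schedule(), cyc$times[1],
                       cyc$times[1] + 12 * 24, dt = 0.05, y0 = y0,
                       rtol = 1e-9, atol = 1e-11)
  dev <- vapply(1:10, function(d) {
    sel <- tr$times >= cyc$times[1] + (d - 1) * 24 &
      tr$times < cyc$times[1] + d * 24
    max(abs(tr$states[sel, "CORT"] - ref$states[sel, "CORT"]))
  }, numeric(1))
  fit <- lm(log(dev) ~ I(24 * (0:9)))
  expect_equal(unname(coef(fit)[2]), fr$leading_exponent,
               tolerance = 0.15)
})

test_that("exponent regression recovers exact linear structure", {
  set.seed(6)
  df <- data.frame(K_p1 = runif(12), K_p2 = runif(12), k_p3 = runif(12))
  df$leading_exponent <- -0.01 - 0.02 * df$K_p1 + 0.005 * df$K_p2 -
    0.03 * df$k_p3
  fit <- suppressWarnings(regress_exponent_on_params(df))  # exact fit
  expect_equal(unname(fit$coefficients),
               c(-0.01, -0.02, 0.005, -0.03), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # permutation invariance
  fit2 <- suppressWarnings(regress_exponent_on_params(df[sample(nrow(df)), ]))
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_error(regress_exponent_on_params(df[1:4, ]), "at least 5")
  df$K_p2 <- df$K_p1
  expect_error(regress_exponent_on_params(df), "rank")
})
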