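cyc <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                transient_days = 8, tol = 1e-3,
                                max_days = 40, dt = 0.05, rtol = 1e-6,
                                atol = 1e-8)

test_that("the mid-inactive onset tracks the CORT acrophase", {
  on <- mid_inactive_onset(cyc)
  expect_equal(on, (cort_peak_phase(cyc) - 7) %% 24)
  expect_true(on >= 0 && on < 24)
})

test_that("a unit-fold stressor produces no response", {
  # fold_increase must exceed 1 by construction; an (almost) unit pulse
  # must give a delta AUC at solver tolerance
  d <- acute_stress_response(default_parameters(),
                             acute_stressor(fold_increase = 1 + 1e-12),
                             cycle = cyc)
  expect_lt(abs(d), 1e-6)
  expect_error(acute_stressor(fold_increase = 1), "fold_increase")
  expect_error(acute_stressor(duration = 0), "duration")
})

test_that("the stress response grows with stressor magnitude", {
  folds <- c(2, 5, 10)
  d <- vapply(folds, function(f)
    acute_stress_response(default_parameters(),
                          acute_stressor(onset = 14, fold_increase = f),
                          cycle = cyc), numeric(1))
  expect_true(all(d > 0))
  expect_true(all(diff(d) > 0))
})

test_that("delta AUC is invariant to extra burn-in once converged", {
  long <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                   transient_days = 25, tol = 1e-4,
                                   dt = 0.05, rtol = 1e-6, atol = 1e-8)
  d1 <- acute_stress_response(default_parameters(), acute_stressor(),
                              cycle = cyc)
  d2 <- acute_stress_response(default_parameters(), acute_stressor(),
                              cycle = long)
  expect_equal(d1, d2, tolerance = 1e-3)
})

test_that("symbolization follows the normal quintile breakpoints", {
  # direct construction: z values placed in each quintile
  v <- c(-3, -0.5, 0, 0.5, 3)
  # use values whose z-scores are the values themselves (mean 0, sd known)
  z <- (v - mean(v)) / sd(v)
  sym <- symbolize(v)
  expect_equal(sym$z, z)
  expect_equal(sym$symbol[sym$z == min(sym$z)], 1L)
  expect_equal(sym$symbol[sym$z == max(sym$z)], 5L)
  # a z of exactly zero sits in the central quintile
  big <- symbolize(c(-2, -1, 0, 1, 2, seq(-1.5, 1.5, by = 0.5)))
  expect_equal(big$symbol[big$z == 0], rep(3L, sum(big$z == 0)))
  expect_error(symbolize(rep(1, 6)), "variance")
})

test_that("symbolization is invariant to affine rescaling", {
  set.seed(33)
  v <- rnorm(50)
  s1 <- symbolize(v)
  s2 <- symbolize(5 + 3 * v)
  expect_equal(s1$z, s2$z, tolerance = 1e-12)
  expect_identical(s1$symbol, s2$symbol)
})

test_that("trivial photoperiod perturbations cost nothing", {
  expect_equal(transient_inversion_phase_shift(default_parameters(),
                                               inversion_hours = 0), 0)
  expect_equal(resynchronization_time(default_parameters(), delay_h = 0), 0)
})

test_that("phase shifts are reported circularly within half a period", {
  shift <- transient_inversion_phase_shift(default_parameters(),
                                           follow_days = 10, cycle = cyc)
  expect_gte(shift, 0)
  expect_lte(shift, 12)
  expect_gt(shift, 0.5)   # a 96 h inversion must move the peak measurably
})

test_that("the system resynchronizes after a 10 h delay", {
  days <- resynchronization_time(default_parameters(), cycle = cyc)
  expect_gte(days, 1)
  expect_lte(days, 60)
  # a vacuous criterion is met immediately
  days_loose <- resynchronization_time(default_parameters(),
                                       criterion_h = 24, persist = 1,
                                       cycle = cyc)
  expect_lte(days_loose, 1)
})
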