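cyc <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                transient_days = 10, tol = 1e-4,
                                dt = 0.05)

test_that("the entrained cycle locks to the 24 h schedule period", {
  expect_true(attr(cyc, "converged"))
  # peak-to-peak interval over several days equals the schedule period
  tr <- integrate_hpa(cyc$params, cyc$schedule, cyc$times[1],
                      cyc$times[1] + 5 * 24, dt = 0.02,
                      y0 = cyc$states[1, ])
  pks <- cort_peak_phase(tr, all = TRUE)
  expect_true(length(pks) >= 4)
  expect_true(all(abs(diff(pks) - 24) < 1e-3))
})

test_that("constant darkness free-runs at a non-24 h period", {
  tau <- free_running_period(default_parameters())
  expect_gt(abs(tau - 24), 0.05)
  dd <- integrate_to_limit_cycle(default_parameters(), constant_darkness(),
                                 transient_days = 10, tol = 1e-3,
                                 dt = 0.05)
  expect_equal(attr(dd, "free_running_period"), tau, tolerance = 1e-3)
})

test_that("infinite tolerance returns after exactly the transient", {
  tr <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                 transient_days = 3, tol = Inf)
  expect_equal(attr(tr, "days_used"), 4)  # transient + the returned cycle
  expect_true(attr(tr, "converged"))
})

test_that("peak extraction is exact on a known cosine and equivariant", {
  t <- seq(0, 48, by = 0.1)
  traj <- fake_trajectory(t, 5 + 2 * cos(2 * pi * (t - 20) / 24))
  expect_equal(cort_peak_phase(traj), 20, tolerance = 0.05)

  shifted <- fake_trajectory(t, 5 + 2 * cos(2 * pi * (t - 23) / 24))
  expect_equal(circular_diff <- hpaclock:::circular_diff(
    cort_peak_phase(shifted), (cort_peak_phase(traj) + 3) %% 24), 0,
    tolerance = 0.05)

  expect_error(cort_peak_phase(fake_trajectory(t, rep(1, length(t)))),
               "constant")
})

test_that("peak time is stable under grid refinement", {
  coarse <- integrate_hpa(cyc$params, cyc$schedule, cyc$times[1],
                          cyc$times[1] + 24, dt = 0.1,
                          y0 = cyc$states[1, ])
  fine <- integrate_hpa(cyc$params, cyc$schedule, cyc$times[1],
                        cyc$times[1] + 24, dt = 0.01,
                        y0 = cyc$states[1, ])
  expect_equal(cort_peak_phase(coarse), cort_peak_phase(fine),
               tolerance = 0.05)
})

test_that("AUC is exact for constant and linear profiles and converges", {
  t <- seq(0, 24, by = 0.1)
  expect_equal(auc_cort(fake_trajectory(t, rep(3, length(t))), 2, 4), 12)
  ramp <- fake_trajectory(t, 1 + 0.5 * t)
  # trapezoid is exact for linear functions: integral of 1 + 0.5 t on [2,6]
  expect_equal(auc_cort(ramp, 2, 4), 4 + 0.5 * (6^2 - 2^2) / 2)
  expect_error(auc_cort(ramp, 22, 4), "outside")

  a1 <- auc_cort(cyc, cyc$times[1] + 10, 4)
  fine <- integrate_hpa(cyc$params, cyc$schedule, cyc$times[1],
                        cyc$times[1] + 24, dt = 0.025,
                        y0 = cyc$states[1, ])
  a2 <- auc_cort(fine, cyc$times[1] + 10, 4)
  expect_equal(a1, a2, tolerance = 1e-4)
})

test_that("halving solver tolerances leaves the converged cycle unchanged", {
  c1 <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                 transient_days = 10, tol = 1e-5,
                                 dt = 0.1, rtol = 1e-8, atol = 1e-10)
  c2 <- integrate_to_limit_cycle(default_parameters(), light_schedule(),
                                 transient_days = 10, tol = 1e-5,
                                 dt = 0.1, rtol = 5e-9, atol = 5e-11)
  amp <- (max(c1$states[, "CORT"]) - min(c1$states[, "CORT"])) / 2
  expect_lt(max(abs(c1$states[, "CORT"] - c2$states[, "CORT"])) / amp,
            1e-4)
})

test_that("tidy export has the expected schema", {
  df <- as.data.frame(cyc)
  expect_named(df, c("time", "variable", "value"))
  expect_true("CORT" %in% df$variable)
})
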