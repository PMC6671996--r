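# Independent reference implementations used as oracles.

# The model equations written out directly in R (independent of the
# compiled implementation used by the package).
reference_rhs <- function(y, p, L, Ld, s = 1) {
  with(as.list(c(y, p)), {
    hill <- k_us * max(light_TCsynth_3, 0)^n /
      (K_M_us^n + max(light_TCsynth_3, 0)^n)
    c(k_t * (L - light_TCsynth_1),
      k_t * (light_TCsynth_1 - light_TCsynth_2),
      k_t * (light_TCsynth_2 - light_TCsynth_3),
      k_t * (Ld - light_TCdeg_1),
      k_t * (light_TCdeg_1 - light_TCdeg_2),
      k_t * (light_TCdeg_2 - light_TCdeg_3),
      hill - k_deg_us * light_effect * (1 + k_eff * light_TCdeg_3),
      s * k_p1 * K_p1 / (K_p1 + DRN) -
        V_d1 * CRH * (1 + light_effect / (1 + light_effect)) / (K_d1 + CRH),
      k_p2 * K_p2 * CRH / (K_p2 + DRN) - V_d2 * ACTH / (K_d2 + ACTH),
      k_p3 * ACTH - V_d3 * CORT / (K_d3 + CORT),
      k_syn_GRm * (1 - DRN / (IC50_GRm + DRN)) - k_deg * GR_mRNA,
      k_syn_GR * GR_mRNA + r_f * k_re * DRN - k_on * CORT * GR -
        k_deg_GR * GR,
      k_on * CORT * GR - k_T * DR,
      k_T * DR - r_f * k_re * DRN)
  })
}

# wrap a CORT series as a trajectory object for feature-extraction tests
fake_trajectory <- function(times, cort, period = 24) {
  st <- matrix(0, length(times), 14)
  colnames(st) <- hpaclock:::.state_names
  st[, "CORT"] <- cort
  structure(list(times = times, states = st,
                 schedule = light_schedule(period = period),
                 params = default_parameters()),
            class = "hpa_trajectory")
}

# Adler phase equation dphi/dt = dw - K sin(phi); locked iff |dw| <= K.
# Returns stroboscopic phases at integer times after burn-in.
adler_strobe <- function(dw, K, burn = 40, obs = 21) {
  f <- function(t, y, parms) list(dw - K * sin(y))
  tt <- seq(0, burn + obs, by = 1)
  out <- deSolve::ode(c(phi = 0.1), tt, f, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-11)
  phases <- out[out[, 1] > burn - 0.5, 2] %% (2 * pi)
  phases
}

# Stuart-Landau oscillator in Cartesian coordinates; limit cycle r = 1,
# nontrivial Floquet exponent exactly -2 * lambda.
sl_f <- function(lambda, omega) function(t, y) {
  r2 <- y[1]^2 + y[2]^2
  c(lambda * y[1] * (1 - r2) - omega * y[2],
    omega * y[1] + lambda * y[2] * (1 - r2))
}
sl_jac <- function(lambda, omega) function(t, y) {
  x <- y[1]; z <- y[2]; r2 <- x^2 + z^2
  matrix(c(lambda * (1 - r2) - 2 * lambda * x^2,
           omega - 2 * lambda * x * z,
           -omega - 2 * lambda * x * z,
           lambda * (1 - r2) - 2 * lambda * z^2), 2, 2)
}

# shared small fixtures (computed once per test file load)
default_triple <- c(K_p1 = 0.3, K_p2 = 0.4, k_p3 = 1.0)
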