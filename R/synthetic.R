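#' Synthetic calibration-target specification
#'
#' Everything needed to generate a surrogate experimental calibration
#' target from the model itself: the generating regulatory triple, the
#' full base parameter set, the noise applied to the cosinor parameters
#' and the acceptance standard deviations.  The defaults mimic the
#' qualitative phenotype used for calibration: an entrained 24 h CORT
#' rhythm with clear amplitude under the 14L:10D schedule, acceptance
#' bands of 10% of mesor and amplitude and 1 h of acrophase.  These are
#' explicitly surrogate values, not experimental ones.
#'
#' @param K_p1,K_p2,k_p3 generating regulatory triple (must lie inside
#'   `box`).
#' @param params base [hpa_parameters()].
#' @param noise_sd standard deviations of the Gaussian perturbation
#'   applied to the generated cosinor (mesor, amplitude, acrophase);
#'   zero by default.
#' @param sd_frac acceptance SD as a fraction of mesor and amplitude.
#' @param sd_acrophase acceptance SD of acrophase (h).
#' @param box sampling box the triple must lie in.
#' @param seed RNG seed for the noise.
#' @return object of class `synthetic_target_spec`.
#' @export
synthetic_target_spec <- function(K_p1 = 0.3, K_p2 = 0.4, k_p3 = 1.0,
                                  params = default_parameters(),
                                  noise_sd = c(mesor = 0, amplitude = 0,
                                               acrophase = 0),
                                  sd_frac = 0.1, sd_acrophase = 1,
                                  box = default_sampling_box(), seed = 1) {
  triple <- c(K_p1 = K_p1, K_p2 = K_p2, k_p3 = k_p3)
  if (any(triple < box[, 1] | triple > box[, 2]))
    stop("generating triple must lie inside the sampling box")
  noise_sd <- noise_sd[c("mesor", "amplitude", "acrophase")]
  stopifnot(all(noise_sd >= 0), sd_frac > 0, sd_acrophase > 0)
  structure(list(triple = triple, params = params, noise_sd = noise_sd,
                 sd_frac = sd_frac, sd_acrophase = sd_acrophase, box = box,
                 seed = seed),
            class = "synthetic_target_spec")
}

# entrained cycle at the spec's generating triple
.generating_cycle <- function(spec, schedule, dt = 0.05) {
  p <- hpa_parameters(K_p1 = spec$triple["K_p1"],
                      K_p2 = spec$triple["K_p2"],
                      k_p3 = spec$triple["k_p3"], base = spec$params)
  integrate_to_limit_cycle(p, schedule, transient_days = 10, tol = 1e-5,
                           dt = dt, rtol = 1e-8, atol = 1e-10)
}

#' Generate a synthetic calibration target
#'
#' Simulates the entrained model at the generating triple, fits a
#' cosinor to the steady-state CORT cycle, perturbs the fitted
#' parameters by seeded Gaussian noise (truncated so the amplitude stays
#' positive) and attaches the acceptance standard deviations.  With zero
#' noise the generating triple passes its own target by construction.
#'
#' @param spec [synthetic_target_spec()].
#' @param schedule [light_schedule()].
#' @return [calibration_target()].
#' @export
make_calibration_target <- function(spec, schedule = light_schedule()) {
  stopifnot(inherits(spec, "synthetic_target_spec"))
  cyc <- .generating_cycle(spec, schedule)
  cf <- fit_cosinor(cyc$times, cyc$states[, "CORT"],
                    period = schedule$period)
  set.seed(spec$seed)
  m <- cf$mesor + rnorm(1, 0, spec$noise_sd["mesor"])
  a <- cf$amplitude + rnorm(1, 0, spec$noise_sd["amplitude"])
  tries <- 0
  while (a <= 0 && tries < 100) {   # truncate: amplitude must stay positive
    a <- cf$amplitude + rnorm(1, 0, spec$noise_sd["amplitude"])
    tries <- tries + 1
  }
  if (a <= 0) a <- cf$amplitude
  phi <- (cf$acrophase + rnorm(1, 0, spec$noise_sd["acrophase"])) %%
    schedule$period
  calibration_target(mesor = m, amplitude = a, acrophase = phi,
                     sd_mesor = spec$sd_frac * abs(m),
                     sd_amplitude = spec$sd_frac * a,
                     sd_acrophase = spec$sd_acrophase,
                     period = schedule$period)
}

#' Generate a noisy synthetic CORT time series
#'
#' Samples the entrained model CORT profile on a regular grid over
#' `n_days` days under the 14L:10D schedule and adds seeded Gaussian
#' observation noise, emulating an experimental corticosterone sampling
#' series suitable for cosinor analysis.
#'
#' @param spec [synthetic_target_spec()].
#' @param sampling_interval grid spacing (h, > 0).
#' @param obs_noise_sd observation noise SD (conc).
#' @param n_days series length (days).
#' @param schedule [light_schedule()].
#' @return data.frame with columns time (h) and CORT.
#' @export
make_noisy_cort_series <- function(spec, sampling_interval = 1,
                                   obs_noise_sd = 0, n_days = 2,
                                   schedule = light_schedule()) {
  stopifnot(sampling_interval > 0, n_days >= 1)
  cyc <- .generating_cycle(spec, schedule, dt = 0.01)
  period <- schedule$period
  # the converged cycle starts at an integer multiple of the period, so
  # relative time equals clock time; extend it periodically
  t_rel <- cyc$times - cyc$times[1]
  grid <- seq(0, n_days * period, by = sampling_interval)
  vals <- approx(t_rel, cyc$states[, "CORT"], xout = grid %% period,
                 rule = 2)$y
  set.seed(spec$seed + 1L)
  data.frame(time = grid, CORT = vals + rnorm(length(grid), 0, obs_noise_sd))
}
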