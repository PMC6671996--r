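#' Acute stressor specification
#'
#' A transient multiplicative elevation of the CRH synthesis rate
#' `k_p1`, the generic surrogate for an acute psychological or
#' physiological stressor.  The default is a 1 h pulse at 5-fold drive.
#'
#' @param onset clock time of exposure (h in `[0, 24)`).
#' @param duration pulse length (h, > 0).
#' @param fold_increase multiplier on `k_p1` during the pulse (> 1).
#' @return object of class `acute_stressor`.
#' @export
acute_stressor <- function(onset = 14, duration = 1, fold_increase = 5) {
  stopifnot(duration > 0, fold_increase > 1, onset >= 0, onset < 24)
  structure(list(onset = onset, duration = duration,
                 fold_increase = fold_increase), class = "acute_stressor")
}

#' Protocol anchor: the mid-inactive-phase stressor onset
#'
#' The canonical time-of-day comparison point for the acute stress
#' response is the middle of the inactive (rest) phase.  For a nocturnal
#' subject whose CORT peaks at the light/dark transition this is the
#' lights-on midpoint, 7 h before the CORT acrophase; the package
#' anchors the onset to the rhythm itself — `hours_before_peak` hours
#' before the entrained CORT peak — so the protocol stays dynamically
#' equivalent whatever clock position the calibrated rhythm adopts.
#'
#' @param cycle converged entrained cycle
#'   ([integrate_to_limit_cycle()]).
#' @param hours_before_peak offset from the CORT peak (h).
#' @return onset clock time (h in `[0, period)`).
#' @export
mid_inactive_onset <- function(cycle, hours_before_peak = 7) {
  (cort_peak_phase(cycle) - hours_before_peak) %% cycle$schedule$period
}

#' Corticosterone response to an acute stressor
#'
#' Converges the system to its entrained limit cycle, then runs matched
#' stressed and unstressed simulations from the identical converged
#' state at the stressor onset.  The response is the difference in area
#' under the CORT curve over exactly `window` hours from onset
#' (stressed minus unstressed).
#'
#' @param params [hpa_parameters()].
#' @param stressor [acute_stressor()].
#' @param schedule [light_schedule()].
#' @param window AUC window (h); the canonical choice is 4 h.
#' @param cycle optional pre-converged limit cycle (from
#'   [integrate_to_limit_cycle()] with matching params/schedule), to
#'   avoid repeated convergence runs in parameter sweeps.
#' @param ... further arguments to [integrate_to_limit_cycle()].
#' @return delta AUC (conc * h).
#' @export
acute_stress_response <- function(params, stressor = acute_stressor(),
                                  schedule = light_schedule(), window = 4,
                                  cycle = NULL, ...) {
  stopifnot(inherits(stressor, "acute_stressor"))
  if (is.null(cycle))
    cycle <- integrate_to_limit_cycle(params, schedule, ...)
  period <- schedule$period
  # converged state at the stressor onset clock time
  t_anchor <- cycle$times[1]
  onset_abs <- t_anchor + ((stressor$onset - t_anchor) %% period)
  i0 <- which.min(abs(cycle$times - onset_abs))
  y_on <- cycle$states[i0, ]
  t_on <- cycle$times[i0]
  horizon <- max(window, stressor$duration) + 0.5
  base <- integrate_hpa(params, schedule, t_on, t_on + horizon, dt = 0.02,
                        y0 = y_on)
  sw <- data.frame(start = t_on, end = t_on + stressor$duration,
                   fold = stressor$fold_increase)
  stressed <- integrate_hpa(params, schedule, t_on, t_on + horizon,
                            dt = 0.02, y0 = y_on, stress_windows = sw)
  auc_cort(stressed, t_on, window) - auc_cort(base, t_on, window)
}

#' Symbolic partitioning of pooled stress responses
#'
#' Z-scores the pooled response values and assigns each to one of five
#' equiprobable regions of the standard normal distribution (breakpoints
#' at the normal quintiles, approximately -0.8416, -0.2533, 0.2533,
#' 0.8416), symbol 1 denoting the lowest quintile and symbol 5 the
#' highest.
#'
#' @param values pooled response values (e.g. delta AUC across all
#'   conditions); length at least 5.
#' @param breakpoints `"normal"` (theoretical quintiles, default) or
#'   `"empirical"` (sample quintiles).
#' @return data.frame with columns value, z, symbol.
#' @export
symbolize <- function(values, breakpoints = c("normal", "empirical")) {
  breakpoints <- match.arg(breakpoints)
  stopifnot(length(values) >= 5)
  s <- sd(values)
  if (s == 0) stop("zero variance: all pooled responses are equal")
  z <- (values - mean(values)) / s
  br <- if (breakpoints == "normal") qnorm(c(0.2, 0.4, 0.6, 0.8))
        else quantile(z, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  data.frame(value = values, z = z,
             symbol = findInterval(z, br) + 1L)
}

# daily refined CORT peak times of a multi-day trajectory
.daily_peaks <- function(traj) {
  pks <- cort_peak_phase(traj, all = TRUE)
  pks
}

#' Maximal phase shift under a transient light-schedule inversion
#'
#' Simulates temporary shift-work: twin runs from the converged entrained
#' state, one exposed to an inversion of the light/dark cycle lasting
#' `inversion_hours` (starting at the lights-on transition), the control
#' keeping the base schedule.  Returns the maximum circular difference
#' between the daily CORT peak times of the two runs over the protocol
#' and the following `follow_days` days.
#'
#' @param params [hpa_parameters()].
#' @param base base [light_schedule()].
#' @param inversion_hours length of the inverted block (h; default 96).
#' @param follow_days days tracked after the block ends.
#' @param cycle optional pre-converged limit cycle.
#' @param ... passed to [integrate_to_limit_cycle()].
#' @return maximal phase shift (h, in `[0, period/2]`).
#' @export
transient_inversion_phase_shift <- function(params,
                                            base = light_schedule(),
                                            inversion_hours = 96,
                                            follow_days = 20, cycle = NULL,
                                            ...) {
  if (inversion_hours == 0) return(0)
  if (is.null(cycle))
    cycle <- integrate_to_limit_cycle(params, base, ...)
  period <- base$period
  y0 <- cycle$states[nrow(cycle$states), ]
  t0 <- cycle$times[length(cycle$times)]
  start_day <- ceiling(t0 / period) + 1
  t_end <- (start_day + ceiling(inversion_hours / period) +
              follow_days) * period
  pert_sched <- inverted_block(base, start_day, inversion_hours)
  ctrl <- integrate_hpa(params, base, t0, t_end, dt = 0.05, y0 = y0)
  pert <- integrate_hpa(params, pert_sched, t0, t_end, dt = 0.05, y0 = y0)
  pc <- .daily_peaks(ctrl); pp <- .daily_peaks(pert)
  n <- min(length(pc), length(pp))
  if (n == 0) stop("no CORT peaks detected during inversion protocol")
  max(circular_diff(pc[seq_len(n)], pp[seq_len(n)], period))
}

#' Resynchronization time after a permanent light-schedule delay
#'
#' Simulates jet lag: from the converged entrained state the lights-on
#' time is permanently delayed by `delay_h` (default 10 h, moving
#' lights-on to 17:00) with the photoperiod preserved.  Days are counted
#' from the shift until the CORT peak-to-peak interval stays within
#' `criterion_h` (default 3 min = 0.05 h) of the schedule period for
#' `persist` consecutive cycles.
#'
#' @param params [hpa_parameters()].
#' @param base base [light_schedule()].
#' @param delay_h permanent delay of lights-on (h).
#' @param criterion_h re-entrainment criterion on consecutive-peak
#'   spacing (h).
#' @param persist number of consecutive compliant cycles required.
#' @param max_days cap before declaring failure to resynchronize.
#' @param cycle optional pre-converged limit cycle.
#' @param ... passed to [integrate_to_limit_cycle()].
#' @return first day index (0 = already synchronized) at which the
#'   criterion is met.
#' @export
resynchronization_time <- function(params, base = light_schedule(),
                                   delay_h = 10, criterion_h = 0.05,
                                   persist = 3, max_days = 60,
                                   cycle = NULL, ...) {
  if (delay_h == 0) return(0)
  if (is.null(cycle))
    cycle <- integrate_to_limit_cycle(params, base, ...)
  period <- base$period
  y0 <- cycle$states[nrow(cycle$states), ]
  t0 <- cycle$times[length(cycle$times)]
  start_day <- ceiling(t0 / period) + 1
  sched <- delayed_schedule(base, start_day, delay_h)
  t_shift <- start_day * period + base$lights_on
  t_end <- (start_day + max_days + 2) * period
  traj <- integrate_hpa(params, sched, t0, t_end, dt = 0.05, y0 = y0)
  pks <- .daily_peaks(traj)
  pks <- pks[pks > t_shift - period]
  if (length(pks) < persist + 1) stop("too few peaks after the shift")
  spacing_ok <- abs(diff(pks) - period) <= criterion_h
  run <- 0
  for (i in seq_along(spacing_ok)) {
    run <- if (spacing_ok[i]) run + 1 else 0
    if (run >= persist) {
      t_ok <- pks[i + 1 - persist]
      return(max(0, ceiling((t_ok - t_shift) / period)))
    }
  }
  stop(sprintf("no resynchronization within %d days of the %g h delay",
               max_days, delay_h))
}
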