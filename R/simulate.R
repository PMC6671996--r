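.default_solver <- list(rtol = 1e-8, atol = 1e-10, hmax = 0.25)

#' Integrate the HPA model
#'
#' Integrates the compiled model over `[t0, t_end]` with output on a
#' uniform grid.  The integrator is an adaptive Dormand-Prince 5(4)
#' scheme restarted at every light switching time, so the square-wave
#' photic input is handled exactly (no smoothing across discontinuities).
#'
#' @param params [hpa_parameters()].
#' @param schedule [light_schedule()].
#' @param t0,t_end integration window (h).
#' @param dt output grid spacing (h; at most 0.1 for feature extraction).
#' @param y0 initial state (default [default_state()]).
#' @param stress_windows optional data.frame(start, end, fold) of acute
#'   k_p1 pulse windows.
#' @param rtol,atol,hmax solver controls.
#' @return object of class `hpa_trajectory`: list with `times`, `states`
#'   (matrix, one column per state variable), `schedule`, `params`.
#' @export
integrate_hpa <- function(params, schedule = light_schedule(), t0 = 0,
                          t_end = 240, dt = 0.05, y0 = default_state(),
                          stress_windows = NULL,
                          rtol = .default_solver$rtol,
                          atol = .default_solver$atol,
                          hmax = .default_solver$hmax) {
  validate_parameters(unclass(params))
  stopifnot(t_end > t0, dt > 0)
  seg <- schedule_segments(schedule, t0, t_end, stress_windows)
  out_times <- seq(t0, t_end, by = dt)
  st <- cpp_hpa_integrate(as.numeric(unclass(params)), as.numeric(y0),
                          seg$start, seg$L, seg$Ld, seg$s, t_end, out_times,
                          rtol, atol, hmax)
  colnames(st) <- .state_names
  structure(list(times = out_times, states = st, schedule = schedule,
                 params = params), class = "hpa_trajectory")
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat(sprintf("HPA trajectory: %d samples over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  cort <- x$states[, "CORT"]
  cat(sprintf("  CORT range [%.3g, %.3g]\n", min(cort), max(cort)))
  invisible(x)
}

#' Convert a trajectory to a tidy data frame
#'
#' @param x `hpa_trajectory`.
#' @param ... unused.
#' @return data.frame with columns time, variable, value.
#' @export
as.data.frame.hpa_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$states)),
             variable = rep(colnames(x$states), each = length(x$times)),
             value = as.vector(x$states))
}

#' Integrate to the entrained limit cycle
#'
#' Integrates day by day (in units of the schedule period), discarding at
#' least `transient_days`, until two consecutive cycles of the CORT
#' profile agree in sup-norm relative to the cycle amplitude within
#' `tol`.  Returns one converged steady-state cycle.
#'
#' @inheritParams integrate_hpa
#' @param transient_days minimum number of discarded cycles (>= 1).
#' @param tol relative sup-norm convergence tolerance (`Inf` to return
#'   after exactly `transient_days`).
#' @param max_days hard cap on the number of cycles before declaring
#'   non-convergence.
#' @param dt output grid spacing for the returned cycle.
#' @return an `hpa_trajectory` covering one period, with attributes
#'   `converged`, `residual` and `days_used`; the trajectory's time axis
#'   is absolute (so clock time = time mod period still holds).
#' @export
integrate_to_limit_cycle <- function(params, schedule = light_schedule(),
                                     transient_days = 8, tol = 1e-4,
                                     max_days = 200, dt = 0.05,
                                     y0 = default_state(),
                                     rtol = .default_solver$rtol,
                                     atol = .default_solver$atol) {
  stopifnot(transient_days >= 1)
  if (schedule$amplitude == 0)
    return(.limit_cycle_free_running(params, schedule, transient_days, tol,
                                     max_days, dt, y0, rtol, atol))
  period <- schedule$period
  # burn through the transient in one call
  tr <- integrate_hpa(params, schedule, 0, transient_days * period,
                      dt = period / 2, y0 = y0, rtol = rtol, atol = atol)
  y <- tr$states[nrow(tr$states), ]
  t_cur <- transient_days * period
  prev <- NULL
  residual <- Inf
  day <- transient_days
  repeat {
    cyc <- integrate_hpa(params, schedule, t_cur, t_cur + period, dt = dt,
                         y0 = y, rtol = rtol, atol = atol)
    cort <- cyc$states[, "CORT"]
    if (!is.null(prev)) {
      amp <- (max(cort) - min(cort)) / 2
      residual <- if (amp > 0) max(abs(cort - prev)) / amp
                  else max(abs(cort - prev))
      if (is.infinite(tol) || residual < tol) {
        attr(cyc, "converged") <- TRUE
        attr(cyc, "residual") <- residual
        attr(cyc, "days_used") <- day + 1
        return(cyc)
      }
    } else if (is.infinite(tol)) {
      attr(cyc, "converged") <- TRUE
      attr(cyc, "residual") <- NA_real_
      attr(cyc, "days_used") <- day + 1
      return(cyc)
    }
    prev <- cort
    y <- cyc$states[nrow(cyc$states), ]
    t_cur <- t_cur + period
    day <- day + 1
    if (day >= max_days)
      stop(sprintf(
        "limit cycle did not converge within %d days (last residual %.3g)",
        max_days, residual))
  }
}

# Unforced (constant-darkness) branch: the free-running period differs from
# the reference period, so convergence is declared on the stability of the
# peak-to-peak interval and cycle amplitude instead of fixed windows.  The
# returned trajectory covers one intrinsic cycle ending at the last peak.
.limit_cycle_free_running <- function(params, schedule, transient_days, tol,
                                      max_days, dt, y0, rtol, atol) {
  period <- schedule$period
  block <- 6 * period
  tr <- integrate_hpa(params, schedule, 0, transient_days * period,
                      dt = period / 2, y0 = y0, rtol = rtol, atol = atol)
  y <- tr$states[nrow(tr$states), ]
  t_cur <- transient_days * period
  day <- transient_days
  residual <- Inf
  repeat {
    seg <- integrate_hpa(params, schedule, t_cur, t_cur + block, dt = dt,
                         y0 = y, rtol = rtol, atol = atol)
    pks <- cort_peak_phase(seg, all = TRUE)
    if (length(pks) >= 4) {
      intervals <- diff(pks)
      k <- length(intervals)
      residual <- abs(intervals[k] - intervals[k - 1]) / intervals[k]
      if (is.infinite(tol) || residual < tol) {
        tau <- intervals[k]
        sel <- seg$times >= pks[length(pks)] - tau &
          seg$times <= pks[length(pks)]
        cyc <- structure(list(times = seg$times[sel],
                              states = seg$states[sel, , drop = FALSE],
                              schedule = schedule, params = params),
                         class = "hpa_trajectory")
        attr(cyc, "converged") <- TRUE
        attr(cyc, "residual") <- residual
        attr(cyc, "days_used") <- day
        attr(cyc, "free_running_period") <- tau
        return(cyc)
      }
    }
    y <- seg$states[nrow(seg$states), ]
    t_cur <- t_cur + block
    day <- day + block / period
    if (day >= max_days)
      stop(sprintf(
        "limit cycle did not converge within %d days (last residual %.3g)",
        max_days, residual))
  }
}

#' Free-running period in constant darkness
#'
#' Mean corticosterone peak-to-peak interval of the converged unforced
#' oscillation.
#'
#' @inheritParams integrate_to_limit_cycle
#' @param days simulated days after the transient used for averaging.
#' @return period (h).
#' @export
free_running_period <- function(params, transient_days = 15, days = 10,
                                dt = 0.02, rtol = .default_solver$rtol,
                                atol = .default_solver$atol) {
  sch <- constant_darkness()
  tr <- integrate_hpa(params, sch, 0, transient_days * 24, dt = 1,
                      rtol = rtol, atol = atol)
  y <- tr$states[nrow(tr$states), ]
  seg <- integrate_hpa(params, sch, transient_days * 24,
                       (transient_days + days) * 24, dt = dt, y0 = y,
                       rtol = rtol, atol = atol)
  pks <- cort_peak_phase(seg, all = TRUE)
  if (length(pks) < 3) stop("too few oscillation peaks to estimate period")
  mean(diff(pks))
}

# local maxima exceeding a prominence fraction of the range; interior only
.find_peaks <- function(x, prominence = 0.2) {
  i <- which(diff(sign(diff(x))) == -2) + 1
  rng <- max(x) - min(x)
  if (rng <= 0) return(integer(0))
  i[x[i] > min(x) + prominence * rng]
}

# quadratic interpolation through the three samples bracketing index i
.refine_peak <- function(t, x, i) {
  if (i <= 1 || i >= length(x)) return(t[i])
  dt1 <- t[i + 1] - t[i]
  a <- x[i - 1]; b <- x[i]; c <- x[i + 1]
  denom <- a - 2 * b + c
  if (denom == 0) return(t[i])
  t[i] + 0.5 * dt1 * (a - c) / denom
}

#' CORT peak clock time of a trajectory
#'
#' Peak time of the corticosterone profile, refined by quadratic
#' interpolation through the three samples bracketing the discrete
#' maximum, reported as clock time (h modulo the schedule period).
#'
#' @param traj `hpa_trajectory` containing at least one full cycle.
#' @param all if `TRUE`, return all prominent peak times (absolute h)
#'   rather than the clock time of the global maximum.
#' @return clock hour of the peak (or vector of absolute peak times).
#' @export
cort_peak_phase <- function(traj, all = FALSE) {
  cort <- traj$states[, "CORT"]
  if (max(cort) - min(cort) <= .Machine$double.eps * max(1, max(cort)))
    stop("CORT profile is constant; no peak")
  if (all) {
    idx <- .find_peaks(cort)
    return(vapply(idx, function(i) .refine_peak(traj$times, cort, i),
                  numeric(1)))
  }
  i <- which.max(cort)
  if (i == 1 || i == length(cort)) {
    # wrap the periodic cycle so the maximum is interior
    n <- length(cort) - 1
    cortw <- c(cort[(n - 1):n], cort[1:n], cort[1:2])
    tw <- c(traj$times[1] - 2:1 * (traj$times[2] - traj$times[1]),
            traj$times[1:n],
            traj$times[n] + (1:2) * (traj$times[2] - traj$times[1]))
    i <- which.max(cortw)
    return(.refine_peak(tw, cortw, i) %% traj$schedule$period)
  }
  .refine_peak(traj$times, cort, i) %% traj$schedule$period
}

#' Per-cycle summary features
#'
#' Peak and trough clock times (quadratically refined), amplitude
#' (half peak-to-trough range), mean level and period (mean prominent
#' peak-to-peak spacing; `NA` when fewer than two peaks are present).
#'
#' @param traj `hpa_trajectory`.
#' @return data.frame with one row: peak_time, trough_time, amplitude,
#'   mesor, period.
#' @export
cycle_features <- function(traj) {
  cort <- traj$states[, "CORT"]
  t <- traj$times
  pk <- cort_peak_phase(traj)
  i_tr <- which.min(cort)
  trough <- if (i_tr > 1 && i_tr < length(cort))
    .refine_peak(t, -cort, i_tr) %% traj$schedule$period
  else t[i_tr] %% traj$schedule$period
  pks <- cort_peak_phase(traj, all = TRUE)
  per <- if (length(pks) >= 2) mean(diff(pks)) else NA_real_
  data.frame(peak_time = pk, trough_time = trough,
             amplitude = (max(cort) - min(cort)) / 2,
             mesor = mean(cort), period = per)
}

#' Area under the CORT curve
#'
#' Trapezoidal integral of the corticosterone profile over
#' `[t0, t0 + window]`.
#'
#' @param traj `hpa_trajectory`.
#' @param t0 window start (absolute h, inside the trajectory support).
#' @param window window length (h); the canonical stress-response window
#'   is 4 h.
#' @return area (conc * h).
#' @export
auc_cort <- function(traj, t0, window = 4) {
  t1 <- t0 + window
  if (t0 < min(traj$times) - 1e-9 || t1 > max(traj$times) + 1e-9)
    stop("AUC window [", t0, ", ", t1, "] outside trajectory support")
  t <- traj$times
  x <- traj$states[, "CORT"]
  sel <- t >= t0 & t <= t1
  ts <- t[sel]; xs <- x[sel]
  # close the window ends exactly by linear interpolation
  if (length(ts) == 0 || ts[1] > t0) {
    ts <- c(t0, ts); xs <- c(approx(t, x, t0)$y, xs)
  }
  if (ts[length(ts)] < t1) {
    ts <- c(ts, t1); xs <- c(xs, approx(t, x, t1)$y)
  }
  sum(diff(ts) * (head(xs, -1) + tail(xs, -1)) / 2)
}
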