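#' Phase-lock classification from a stroboscopic phase sequence
#'
#' Given one phase observation per entrainer cycle (peak time modulo the
#' entrainer period), the oscillator is declared 1:1 phase-locked when
#' the circular cycle-to-cycle phase drift stays below `tol` (h per
#' cycle) for the final `n_consec` cycles.  This is the classifier used
#' by [is_entrained()]; it applies to any forced oscillator whose phase
#' can be read off stroboscopically.
#'
#' @param phases per-cycle phases (h, in `[0, period)`); `NA` entries
#'   (cycles without an identifiable peak) fail the classification.
#' @param period entrainer period (h).
#' @param tol maximal circular drift per cycle (h).
#' @param n_consec number of final consecutive cycles required.
#' @return logical.
#' @export
phase_locked <- function(phases, period, tol = 0.05, n_consec = 20) {
  if (length(phases) < n_consec + 1) return(FALSE)
  ph <- tail(phases, n_consec + 1)
  if (anyNA(ph)) return(FALSE)
  drift <- circular_diff(ph[-1], ph[-length(ph)], period)
  all(drift < tol)
}

# stroboscopic CORT peak phase per entrainer cycle over [t0, t1]
.strobe_phases <- function(traj, period, t0) {
  pks <- tryCatch(cort_peak_phase(traj, all = TRUE),
                  error = function(e) numeric(0))
  ncyc <- floor((max(traj$times) - t0) / period)
  phases <- rep(NA_real_, ncyc)
  if (length(pks) == 0) return(phases)
  cort <- traj$states[, "CORT"]
  val <- approx(traj$times, cort, pks)$y
  cyc <- floor((pks - t0) / period) + 1
  keep <- cyc >= 1 & cyc <= ncyc
  pks <- pks[keep]; val <- val[keep]; cyc <- cyc[keep]
  for (k in unique(cyc)) {
    sel <- cyc == k
    phases[k] <- (pks[sel][which.max(val[sel])]) %% period
  }
  phases
}

# schedule for an entrainer of arbitrary period/strength: the photoperiod
# fraction (14/24) of the nominal schedule is preserved and the square-wave
# amplitude carries the strength factor
.entrainer_schedule <- function(base, entrainer_period, strength) {
  f <- entrainer_period / base$period
  light_schedule(lights_on = base$lights_on * f,
                 lights_off = base$lights_off * f,
                 period = entrainer_period,
                 amplitude = strength,
                 light_deg_signal = base$light_deg_signal)
}

#' 1:1 entrainment test
#'
#' Drives the photic pathway with a square-wave entrainer of the given
#' period and relative strength (amplitude multiplier on the nominal
#' light square wave, preserving the photoperiod fraction), then tests
#' for 1:1 phase locking of the CORT peak via [phase_locked()] after a
#' burn-in.
#'
#' @param params [hpa_parameters()].
#' @param entrainer_period entrainer period (h).
#' @param entrainer_strength relative amplitude (>= 0; 0 means constant
#'   darkness, which cannot lock).
#' @param base reference [light_schedule()] providing the photoperiod
#'   fraction.
#' @param burn_cycles,obs_cycles burn-in and observation lengths
#'   (entrainer cycles).
#' @param tol drift tolerance (h per cycle).
#' @param rtol,atol solver tolerances.
#' @return `TRUE`/`FALSE`, or `NA` when the trajectory yields no
#'   classifiable peak sequence (flagged separately from "not
#'   entrained").
#' @export
is_entrained <- function(params, entrainer_period,
                         entrainer_strength = 1,
                         base = light_schedule(), burn_cycles = 40,
                         obs_cycles = 20, tol = 0.05, rtol = 1e-6,
                         atol = 1e-8) {
  stopifnot(entrainer_strength >= 0, entrainer_period > 0)
  sched <- if (entrainer_strength > 0)
    .entrainer_schedule(base, entrainer_period, entrainer_strength)
  else constant_darkness(entrainer_period)
  Tn <- entrainer_period
  burn <- integrate_hpa(params, sched, 0, burn_cycles * Tn, dt = Tn / 2,
                        rtol = rtol, atol = atol)
  y <- burn$states[nrow(burn$states), ]
  t0 <- burn_cycles * Tn
  obs <- integrate_hpa(params, sched, t0, t0 + obs_cycles * Tn, dt = 0.05,
                       y0 = y, rtol = rtol, atol = atol)
  rng <- diff(range(obs$states[, "CORT"]))
  if (rng < 1e-8) return(NA)
  phases <- .strobe_phases(obs, Tn, t0)
  if (all(is.na(phases))) return(NA)
  phase_locked(phases, Tn, tol = tol, n_consec = min(obs_cycles - 1, 15))
}

#' Arnold tongue (domain of entrainment)
#'
#' Cell-wise [is_entrained()] over a grid of entrainer periods and
#' relative strengths.  The unforced system's intrinsic period `tau` and
#' CORT amplitude `A0` are recorded for axis normalization (t / tau and
#' A / A0).
#'
#' @param params [hpa_parameters()].
#' @param period_grid entrainer periods (h).
#' @param strength_grid relative entrainer amplitudes.
#' @param base reference schedule.
#' @param ... passed to [is_entrained()].
#' @return object of class `tongue_grid`: list with `periods`,
#'   `strengths`, `entrained` (logical matrix periods x strengths, `NA`
#'   for unclassifiable cells), `tau`, `A0`.
#' @export
arnold_tongue <- function(params, period_grid = seq(20, 28, by = 1),
                          strength_grid = seq(0.25, 1.5, by = 0.25),
                          base = light_schedule(), ...) {
  stopifnot(length(period_grid) > 0, length(strength_grid) > 0)
  dd <- integrate_to_limit_cycle(params, constant_darkness(),
                                 transient_days = 10, tol = 1e-3,
                                 max_days = 80, dt = 0.05,
                                 rtol = 1e-6, atol = 1e-8)
  tau <- attr(dd, "free_running_period")
  A0 <- (max(dd$states[, "CORT"]) - min(dd$states[, "CORT"])) / 2
  ent <- matrix(NA, length(period_grid), length(strength_grid),
                dimnames = list(signif(period_grid, 6),
                                signif(strength_grid, 6)))
  for (j in seq_along(strength_grid))
    for (i in seq_along(period_grid))
      ent[i, j] <- tryCatch(
        is_entrained(params, period_grid[i], strength_grid[j], base, ...),
        error = function(e) NA)
  structure(list(periods = period_grid, strengths = strength_grid,
                 entrained = ent, tau = tau, A0 = A0),
            class = "tongue_grid")
}

#' @export
print.tongue_grid <- function(x, ...) {
  cat(sprintf(
    "Arnold tongue: %d x %d grid, tau = %.3f h, A0 = %.3f; %d/%d entrained\n",
    length(x$periods), length(x$strengths), x$tau, x$A0,
    sum(x$entrained, na.rm = TRUE), length(x$entrained)))
  invisible(x)
}

#' Area of the entrained domain
#'
#' Sum of entrained grid cells weighted by the cell footprint in the
#' (period, strength) plane (unclassifiable `NA` cells count as not
#' entrained).  Comparable across tongues computed on identical grids.
#'
#' @param tongue `tongue_grid`.
#' @param normalized if `TRUE`, measure the footprint on the normalized
#'   axes (period / tau, strength).
#' @return area.
#' @export
tongue_area <- function(tongue, normalized = FALSE) {
  dp <- if (length(tongue$periods) > 1) mean(diff(tongue$periods)) else 1
  ds <- if (length(tongue$strengths) > 1) mean(diff(tongue$strengths)) else 1
  if (normalized) dp <- dp / tongue$tau
  sum(tongue$entrained, na.rm = TRUE) * dp * ds
}

#' Tidy export of a tongue grid
#'
#' @param x `tongue_grid`.
#' @param ... unused.
#' @return data.frame with period, strength, entrained, period_rel
#'   (t / tau).
#' @export
as.data.frame.tongue_grid <- function(x, ...) {
  data.frame(period = rep(x$periods, length(x$strengths)),
             strength = rep(x$strengths, each = length(x$periods)),
             entrained = as.vector(x$entrained),
             period_rel = rep(x$periods, length(x$strengths)) / x$tau)
}
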