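#' Light-dark schedule
#'
#' Describes the square-wave photic input.  The default is the 14 h
#' light : 10 h dark schedule with lights on 07:00-21:00 used throughout
#' the analyses.  `overrides` is an ordered list of temporary schedule
#' blocks used by the perturbation protocols (shift-work inversion,
#' permanent jet-lag delay); each element is a list with fields
#' `start`, `end` (absolute simulation time, h; `end = Inf` for a
#' permanent change), `lights_on`, `lights_off` (clock h within the
#' period).
#'
#' `light_deg_signal` selects the drive of the photic degradation
#' transfer chain: `"dark"` (default; the chain is driven by darkness,
#' `1 - light`, so the photic effect shuts off sharply after lights-off)
#' or `"light"` (the chain is driven by the same square wave as the
#' synthesis chain).
#'
#' @param lights_on,lights_off clock time (h in `[0, period)`).
#' @param period entrainer period (h).
#' @param amplitude light amplitude (relative entrainer strength; 1 for
#'   the nominal schedule, 0 for constant darkness).
#' @param light_deg_signal `"dark"` or `"light"`.
#' @param overrides list of override blocks (see Details).
#' @return an object of class `light_schedule`.
#' @examples
#' light_schedule()                      # 14L:10D, lights on 07:00
#' constant_darkness()
#' @export
light_schedule <- function(lights_on = 7, lights_off = 21, period = 24,
                           amplitude = 1, light_deg_signal = c("dark", "light"),
                           overrides = list()) {
  light_deg_signal <- match.arg(light_deg_signal)
  stopifnot(period > 0, lights_on >= 0, lights_on < period,
            lights_off >= 0, lights_off < period, amplitude >= 0)
  photo <- (lights_off - lights_on) %% period
  if (photo <= 0 || photo >= period)
    stop("photoperiod length must lie strictly inside (0, period)")
  for (ov in overrides)
    stopifnot(is.list(ov), all(c("start", "end", "lights_on",
                                 "lights_off") %in% names(ov)))
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 period = period, amplitude = amplitude,
                 light_deg_signal = light_deg_signal,
                 overrides = overrides),
            class = "light_schedule")
}

#' @rdname light_schedule
#' @export
constant_darkness <- function(period = 24) {
  s <- light_schedule(period = period, amplitude = 0)
  s
}

#' @export
print.light_schedule <- function(x, ...) {
  if (x$amplitude == 0) {
    cat(sprintf("Light schedule: constant darkness (reference period %g h)\n",
                x$period))
  } else {
    cat(sprintf(
      "Light schedule: lights on %05.2f-%05.2f, period %g h, amplitude %g\n",
      x$lights_on, x$lights_off, x$period, x$amplitude))
  }
  if (length(x$overrides))
    cat(sprintf("  with %d override block(s)\n", length(x$overrides)))
  invisible(x)
}

.active_window <- function(schedule, t) {
  on <- schedule$lights_on; off <- schedule$lights_off
  for (ov in schedule$overrides) {
    if (t >= ov$start && t < ov$end) {
      on <- ov$lights_on; off <- ov$lights_off
    }
  }
  c(on = on, off = off)
}

#' Square-wave light signal
#'
#' Value of the photic square wave at time `t`: `amplitude` during the
#' lit interval of the schedule active at `t` (including overrides),
#' else 0.
#'
#' @param t time (h, from simulation start); vectorized.
#' @param schedule a [light_schedule()].
#' @return numeric vector of 0 / amplitude values.
#' @examples
#' light_signal(12, light_schedule())   # 1, lit interval
#' light_signal(22, light_schedule())   # 0, dark
#' @export
light_signal <- function(t, schedule = light_schedule()) {
  stopifnot(all(t >= 0))
  if (schedule$amplitude == 0) return(rep(0, length(t)))
  vapply(t, function(ti) {
    w <- .active_window(schedule, ti)
    tc <- ti %% schedule$period
    lit <- if (w["on"] <= w["off"]) (tc >= w["on"] && tc < w["off"])
           else (tc >= w["on"] || tc < w["off"])
    if (lit) schedule$amplitude else 0
  }, numeric(1))
}

# Piecewise-constant forcing segments on [t0, t1]: a data.frame with the
# segment start times and the (light, light_deg, kp1_scale) values held on
# each segment.  The integrator restarts at every segment boundary, so the
# square wave is handled without smoothing.
schedule_segments <- function(schedule, t0, t1, stress_windows = NULL) {
  period <- schedule$period
  breaks <- c(t0, t1)
  # base on/off transitions
  k0 <- floor(t0 / period) - 1; k1 <- ceiling(t1 / period) + 1
  for (k in k0:k1)
    breaks <- c(breaks, k * period + schedule$lights_on,
                k * period + schedule$lights_off)
  for (ov in schedule$overrides) {
    breaks <- c(breaks, ov$start, ov$end)
    for (k in k0:k1)
      breaks <- c(breaks, k * period + ov$lights_on,
                  k * period + ov$lights_off)
  }
  if (!is.null(stress_windows))
    breaks <- c(breaks, stress_windows$start, stress_windows$end)
  breaks <- sort(unique(breaks[is.finite(breaks) & breaks >= t0 &
                                 breaks <= t1]))
  starts <- breaks[-length(breaks)]
  mid <- starts + diff(breaks) / 2
  L <- light_signal(mid, schedule)
  Ld <- if (schedule$light_deg_signal == "dark") {
    # darkness complement, scaled by the entrainer amplitude; identically 0
    # in constant darkness so the whole photic subsystem stays at rest
    if (schedule$amplitude > 0) schedule$amplitude - L else rep(0, length(L))
  } else L
  s <- rep(1, length(starts))
  if (!is.null(stress_windows)) {
    for (i in seq_len(nrow(stress_windows))) {
      sel <- mid >= stress_windows$start[i] & mid < stress_windows$end[i]
      s[sel] <- s[sel] * stress_windows$fold[i]
    }
  }
  list(start = starts, L = L, Ld = Ld, s = s, t_end = t1)
}

#' Schedule perturbations used by the photoperiod protocols
#'
#' `inverted_block()` adds a temporary inversion of the light/dark cycle
#' (lights on during the former dark phase) lasting `duration_h` hours,
#' starting at the lights-on transition of `start_day` (days counted from
#' simulation start).  `delayed_schedule()` applies a permanent delay of
#' the lights-on time by `delay_h` hours from `start_day`, preserving the
#' photoperiod length.
#'
#' @param schedule base [light_schedule()].
#' @param start_day day index (0-based) at which the perturbation starts.
#' @param duration_h length of the inverted block (h).
#' @param delay_h permanent delay of lights-on (h).
#' @return a new `light_schedule` with the override attached.
#' @export
inverted_block <- function(schedule, start_day, duration_h = 96) {
  t0 <- start_day * schedule$period + schedule$lights_on
  ov <- list(start = t0, end = t0 + duration_h,
             lights_on = schedule$lights_off,
             lights_off = schedule$lights_on)
  schedule$overrides <- c(schedule$overrides, list(ov))
  schedule
}

#' @rdname inverted_block
#' @export
delayed_schedule <- function(schedule, start_day, delay_h = 10) {
  t0 <- start_day * schedule$period + schedule$lights_on
  on <- (schedule$lights_on + delay_h) %% schedule$period
  off <- (schedule$lights_off + delay_h) %% schedule$period
  ov <- list(start = t0, end = Inf, lights_on = on, lights_off = off)
  schedule$overrides <- c(schedule$overrides, list(ov))
  schedule
}
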