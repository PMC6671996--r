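#' Single-component cosinor fit
#'
#' Least-squares fit of `M + A cos(2 pi (t - phi) / period)` via the
#' linear reparameterization `M + b cos(w t) + g sin(w t)`, followed by
#' back-transformation.  The amplitude is reported nonnegative and the
#' acrophase normalized to `[0, period)`.
#'
#' @param times sample times (h); at least 4 samples spanning at least
#'   one period.
#' @param values measurements (conc).
#' @param period fixed fitting period (h, default 24).
#' @return object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase`, `period`, `se` (standard errors of mesor, amplitude,
#'   acrophase from the linear-model covariance via the delta method) and
#'   `fit` (the underlying `lm`).
#' @examples
#' t <- 0:23
#' y <- 5 + 2 * cos(2 * pi * (t - 20) / 24)
#' fit_cosinor(t, y)
#' @export
fit_cosinor <- function(times, values, period = 24) {
  stopifnot(length(times) == length(values))
  if (length(times) < 4) stop("need at least 4 samples")
  if (diff(range(times)) < period - 1e-9)
    stop("samples must span at least one period")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  if (qr(X)$rank < 3)
    stop("degenerate cosinor design (aliased sampling times)")
  fit <- lm.fit(X, values)
  b <- fit$coefficients
  M <- b[1]; A <- sqrt(b[2]^2 + b[3]^2)
  phi <- if (A > 0) (atan2(b[3], b[2]) %% (2 * pi)) / w else 0
  # delta-method standard errors from the linear-model covariance
  dof <- length(values) - 3
  se <- c(NA_real_, NA_real_, NA_real_)
  if (dof > 0) {
    s2 <- sum(fit$residuals^2) / dof
    V <- s2 * chol2inv(qr.R(qr(X)))
    se_M <- sqrt(V[1, 1])
    if (A > 0) {
      gA <- c(0, b[2] / A, b[3] / A)
      gphi <- c(0, -b[3] / A^2, b[2] / A^2) / w
      se <- c(se_M, sqrt(drop(t(gA) %*% V %*% gA)),
              sqrt(drop(t(gphi) %*% V %*% gphi)))
    } else se <- c(se_M, sqrt(V[2, 2]), NA_real_)
  }
  structure(list(mesor = unname(M), amplitude = unname(A),
                 acrophase = unname(phi), period = period,
                 se = setNames(se, c("mesor", "amplitude", "acrophase")),
                 coefficients = unname(b)),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h): mesor %.4g, amplitude %.4g, acrophase %05.2f h\n",
    x$period, x$mesor, x$amplitude, x$acrophase))
  invisible(x)
}

#' Evaluate the fitted cosine curve
#'
#' @param object `cosinor_fit`.
#' @param times evaluation times (h).
#' @param ... unused.
#' @return fitted values.
#' @export
predict.cosinor_fit <- function(object, times, ...) {
  object$mesor + object$amplitude *
    cos(2 * pi * (times - object$acrophase) / object$period)
}

# circular distance between two clock hours on a cycle of given period
circular_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Calibration target
#'
#' The cosinor parameters of the reference corticosterone profile and the
#' per-parameter standard deviations defining the acceptance band
#' (simulated profiles must match within +/- 1 SD on each parameter).
#'
#' @param mesor,amplitude,acrophase target cosinor parameters.
#' @param sd_mesor,sd_amplitude,sd_acrophase acceptance standard
#'   deviations (all > 0); acrophase is compared circularly.
#' @param period fitting period (h).
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(mesor, amplitude, acrophase, sd_mesor,
                               sd_amplitude, sd_acrophase, period = 24) {
  stopifnot(sd_mesor > 0, sd_amplitude > 0, sd_acrophase > 0,
            amplitude >= 0)
  structure(list(mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase %% period,
                 sd = c(mesor = sd_mesor, amplitude = sd_amplitude,
                        acrophase = sd_acrophase),
                 period = period),
            class = "calibration_target")
}

#' @export
print.calibration_target <- function(x, ...) {
  cat(sprintf(
    "Calibration target: mesor %.4g (sd %.3g), amplitude %.4g (sd %.3g), acrophase %05.2f h (sd %.3g h)\n",
    x$mesor, x$sd["mesor"], x$amplitude, x$sd["amplitude"], x$acrophase,
    x$sd["acrophase"]))
  invisible(x)
}

#' Calibration acceptance test
#'
#' A fit passes when each cosinor parameter lies within one target
#' standard deviation of the target value; the acrophase deviation is
#' measured circularly (minimum over the 24 h wrap).
#'
#' An additional root-mean-square criterion against the target's cosine
#' curve can be enabled by supplying `rmse_tol`: the RMS difference
#' between the fitted and the target cosine over one period (dense
#' grid) must then also stay below the tolerance.  It is off by
#' default; the per-parameter box is the primary criterion.
#'
#' @param fit `cosinor_fit` (or list with mesor/amplitude/acrophase).
#' @param target [calibration_target()].
#' @param rmse_tol optional RMSE tolerance (conc) against the target
#'   cosine curve; `NULL` (default) disables the check.
#' @return logical.
#' @export
passes_calibration <- function(fit, target, rmse_tol = NULL) {
  ok_m <- abs(fit$mesor - target$mesor) <= target$sd["mesor"]
  ok_a <- abs(fit$amplitude - target$amplitude) <= target$sd["amplitude"]
  ok_p <- circular_diff(fit$acrophase, target$acrophase, target$period) <=
    target$sd["acrophase"]
  ok <- unname(ok_m && ok_a && ok_p)
  if (ok && !is.null(rmse_tol)) {
    tt <- seq(0, target$period, length.out = 241)
    w <- 2 * pi / target$period
    yf <- fit$mesor + fit$amplitude * cos(w * (tt - fit$acrophase))
    yt <- target$mesor + target$amplitude * cos(w * (tt - target$acrophase))
    ok <- sqrt(mean((yf - yt)^2)) <= rmse_tol
  }
  ok
}

#' Write / read a calibration target as YAML
#'
#' @param target [calibration_target()].
#' @param path file path.
#' @return the target (invisibly for write).
#' @export
write_calibration_target <- function(target, path) {
  yaml::write_yaml(list(mesor = target$mesor, amplitude = target$amplitude,
                        acrophase = target$acrophase, period = target$period,
                        sd = as.list(target$sd)), path)
  invisible(target)
}

#' @rdname write_calibration_target
#' @export
read_calibration_target <- function(path) {
  x <- yaml::read_yaml(path)
  calibration_target(x$mesor, x$amplitude, x$acrophase, x$sd$mesor,
                     x$sd$amplitude, x$sd$acrophase, x$period)
}
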