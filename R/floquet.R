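#' Monodromy matrix of an arbitrary periodic orbit
#'
#' Integrates the variational system `dPhi/dt = J(t, y) Phi` alongside
#' the orbit over one period with `deSolve`, starting from the identity.
#' Intended for small reference systems (validation oracles); the HPA
#' model uses a dedicated compiled path in [floquet_exponents()].
#'
#' @param f function(t, y) returning the derivative vector.
#' @param jac function(t, y) returning the Jacobian matrix.
#' @param y0 state on the periodic orbit.
#' @param period orbit period.
#' @param t0 starting time.
#' @param rtol,atol solver tolerances.
#' @return the monodromy matrix.
#' @export
monodromy_matrix <- function(f, jac, y0, period, t0 = 0, rtol = 1e-10,
                             atol = 1e-12) {
  n <- length(y0)
  aug <- function(t, y, parms) {
    x <- y[1:n]
    Phi <- matrix(y[-(1:n)], n, n)
    list(c(f(t, x), as.vector(jac(t, x) %*% Phi)))
  }
  y_aug <- c(y0, as.vector(diag(n)))
  out <- deSolve::ode(y_aug, c(t0, t0 + period), aug, NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  matrix(out[nrow(out), -1][-(1:n)], n, n)
}

# Newton refinement of the free-running period: solve for the return time
# to the hyperplane through y0 normal to the flow direction f(y0).
.refine_period <- function(params, schedule, y0, tau0, rtol, atol,
                           iters = 4) {
  p <- as.numeric(unclass(params))
  f0 <- cpp_hpa_rhs(p, as.numeric(y0), 0, 0, 1)
  nrm <- f0 / sqrt(sum(f0^2))
  tau <- tau0
  y <- y0
  for (it in seq_len(iters)) {
    traj <- integrate_hpa(params, schedule, 0, tau, dt = tau, y0 = y,
                          rtol = rtol, atol = atol)
    yT <- traj$states[nrow(traj$states), ]
    g <- sum((yT - y0) * nrm)
    fT <- cpp_hpa_rhs(p, as.numeric(yT), 0, 0, 1)
    dg <- sum(fT * nrm)
    tau <- tau - g / dg
    y <- y0
  }
  # one more return-map application to land the anchor on the cycle
  traj <- integrate_hpa(params, schedule, 0, tau, dt = tau, y0 = y0,
                        rtol = rtol, atol = atol)
  list(tau = tau, y0 = traj$states[nrow(traj$states), ])
}

#' Floquet analysis of the HPA limit cycle
#'
#' Builds the monodromy matrix by integrating the 14 x 14 variational
#' system (analytic Jacobian, compiled) along one period of the
#' converged orbit, and reports the Floquet multipliers and exponents
#' `log(multiplier) / period` (1/h).
#'
#' Under periodic light forcing the period is the entrainer period and
#' all multipliers describe stability.  In constant darkness the orbit
#' is autonomous: the free-running period is Newton-refined on a
#' Poincare section, one multiplier equals 1 (neutral phase direction)
#' and is excluded from the leading exponent.
#'
#' @param params [hpa_parameters()].
#' @param schedule [light_schedule()] (amplitude 0 for the autonomous
#'   case).
#' @param transient_days,tol convergence controls for the underlying
#'   limit cycle.
#' @param rtol,atol solver tolerances (tight by default; the variational
#'   integration follows the same controls).
#' @param cond_threshold condition-number threshold above which the
#'   result is flagged ill-conditioned.
#' @return object of class `floquet_result`: list with `multipliers`
#'   (complex), `exponents` (complex, 1/h), `leading_exponent` (real
#'   part, excluding the trivial multiplier when autonomous),
#'   `trivial_multiplier` (autonomous case; `NA` when forced),
#'   `period`, `ill_conditioned`.
#' @export
floquet_exponents <- function(params, schedule = light_schedule(),
                              transient_days = 30, tol = 1e-6,
                              rtol = 1e-10, atol = 1e-12,
                              cond_threshold = 1e18) {
  autonomous <- schedule$amplitude == 0
  cyc <- integrate_to_limit_cycle(params, schedule,
                                  transient_days = transient_days,
                                  tol = tol, max_days = 300, dt = 0.05,
                                  rtol = rtol, atol = atol)
  if (autonomous) {
    tau0 <- attr(cyc, "free_running_period")
    y_anchor <- cyc$states[nrow(cyc$states), ]
    ref <- .refine_period(params, schedule, y_anchor, tau0, rtol, atol)
    period <- ref$tau
    y0 <- ref$y0
    seg <- list(start = 0, L = 0, Ld = 0, s = 1, t_end = period)
  } else {
    period <- schedule$period
    y0 <- cyc$states[1, ]
    t0 <- cyc$times[1]
    seg <- schedule_segments(schedule, t0, t0 + period)
  }
  mono <- cpp_hpa_monodromy(as.numeric(unclass(params)), as.numeric(y0),
                            seg$start, seg$L, seg$Ld, seg$s, seg$t_end,
                            rtol, atol, 0.25)
  M <- mono$monodromy
  ill <- kappa(M) > cond_threshold
  mult <- as.complex(eigen(M, only.values = TRUE)$values)
  ord <- order(Mod(mult), decreasing = TRUE)
  mult <- mult[ord]
  expo <- log(mult) / period
  if (autonomous) {
    i_triv <- which.min(Mod(mult - 1))
    trivial <- mult[i_triv]
    lead <- max(Re(expo[-i_triv]))
  } else {
    trivial <- NA_complex_
    lead <- max(Re(expo))
  }
  structure(list(multipliers = mult, exponents = expo,
                 leading_exponent = lead, trivial_multiplier = trivial,
                 period = period, ill_conditioned = ill),
            class = "floquet_result")
}

#' @export
print.floquet_result <- function(x, ...) {
  cat(sprintf(
    "Floquet result (period %.4f h): leading exponent %.5g 1/h%s\n",
    x$period, x$leading_exponent,
    if (x$ill_conditioned) " [ill-conditioned]" else ""))
  if (!is.na(x$trivial_multiplier))
    cat(sprintf("  trivial multiplier: %.8f\n", Mod(x$trivial_multiplier)))
  cat("  |multipliers|:",
      paste(signif(Mod(x$multipliers)[1:min(5, length(x$multipliers))], 4),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Regression of the leading Floquet exponent on the regulatory triple
#'
#' Ordinary least squares of the leading exponent on (K_p1, K_p2, k_p3),
#' quantifying how the relaxation rate of the entrained orbit depends on
#' the feedback constants and the adrenal sensitivity.
#'
#' @param triples data.frame with columns K_p1, K_p2, k_p3 and
#'   `leading_exponent` (at least 5 rows).
#' @return object of class `floquet_regression`: list with
#'   `coefficients` (b0..b3), `r_squared`, `residuals`, `fit` (the lm).
#' @export
regress_exponent_on_params <- function(triples) {
  need <- c("K_p1", "K_p2", "k_p3", "leading_exponent")
  stopifnot(all(need %in% names(triples)))
  if (nrow(triples) < 5) stop("need at least 5 triples for the regression")
  X <- cbind(1, triples$K_p1, triples$K_p2, triples$k_p3)
  if (qr(X)$rank < 4) stop("rank-deficient regression design")
  fit <- lm(leading_exponent ~ K_p1 + K_p2 + k_p3, data = triples)
  structure(list(coefficients = setNames(coef(fit),
                                         c("b0", "b1_K_p1", "b2_K_p2",
                                           "b3_k_p3")),
                 r_squared = summary(fit)$r.squared,
                 residuals = unname(fit$residuals), fit = fit),
            class = "floquet_regression")
}

#' @export
print.floquet_regression <- function(x, ...) {
  cat("Leading Floquet exponent ~ K_p1 + K_p2 + k_p3\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}
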