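#' Right-hand side of the HPA model ODE system
#'
#' Reference (pure R) implementation of the 14 coupled time-derivatives:
#' the photic input cascade (two three-compartment transfer chains and the
#' ultrasensitive `light_effect` variable), the hormonal cascade
#' CRH -> ACTH -> CORT with receptor-mediated negative feedback, and the
#' glucocorticoid-receptor pharmacodynamics (GR mRNA, free GR, cytosolic
#' and nuclear hormone-receptor complex).  Light enhances CRH degradation
#' through the factor `1 + light_effect / (1 + light_effect)`.
#'
#' The compiled integrator uses an identical C++ implementation; this
#' function is exported for inspection and for cross-checking.
#'
#' @param t time (h).
#' @param y named state vector (see [default_state()]).
#' @param params [hpa_parameters()].
#' @param schedule [light_schedule()].
#' @param kp1_scale multiplier applied to `k_p1` (acute stress pulses).
#' @return list with the derivative vector (deSolve convention).
#' @export
hpa_rhs <- function(t, y, params, schedule = light_schedule(),
                    kp1_scale = 1) {
  if (any(!is.finite(y))) stop("non-finite state")
  if (any(!is.finite(unclass(params)))) stop("non-finite parameters")
  p <- unclass(params)
  L <- light_signal(t, schedule)
  Ld <- if (schedule$light_deg_signal == "dark") {
    if (schedule$amplitude > 0) schedule$amplitude - L else 0
  } else L
  dy <- cpp_hpa_rhs(as.numeric(p), as.numeric(y), L, Ld, kp1_scale)
  list(setNames(dy, .state_names))
}

# Finite-difference Jacobian of the rhs; test oracle for the analytic one.
hpa_jacobian_fd <- function(y, params, L = 0, Ld = 0, s = 1, eps = 1e-7) {
  p <- as.numeric(unclass(params))
  f0 <- cpp_hpa_rhs(p, as.numeric(y), L, Ld, s)
  J <- matrix(0, length(y), length(y))
  for (j in seq_along(y)) {
    h <- eps * max(1, abs(y[j]))
    yp <- as.numeric(y); yp[j] <- yp[j] + h
    ym <- as.numeric(y); ym[j] <- ym[j] - h
    J[, j] <- (cpp_hpa_rhs(p, yp, L, Ld, s) -
                 cpp_hpa_rhs(p, ym, L, Ld, s)) / (2 * h)
  }
  J
}

#' Audit receptor flux conservation
#'
#' Verifies by term evaluation that the receptor fluxes are consistent
#' across the pharmacodynamic equations: the CORT-GR binding flux leaving
#' the free-receptor pool equals the flux entering the cytosolic complex,
#' the translocation flux leaving the cytosolic complex equals the flux
#' entering the nuclear complex, and the recycled nuclear flux re-entering
#' the free-receptor pool equals `r_f * k_re * DRN`.
#'
#' The audit evaluates each equation's copy of the shared term at a set of
#' random nonnegative states and reports any mismatch.
#'
#' @param params [hpa_parameters()].
#' @param n_probe number of random probe states.
#' @param rhs_fun rhs used for the audit (replaceable to exercise the
#'   mismatch reporting with a deliberately broken model).
#' @return object of class `conservation_report` with element `balanced`
#'   (logical) and `mismatches` (character).
#' @export
conservation_audit <- function(params = default_parameters(), n_probe = 20,
                               rhs_fun = NULL) {
  validate_parameters(unclass(params))
  p <- unclass(params)
  if (is.null(rhs_fun))
    rhs_fun <- function(y) cpp_hpa_rhs(as.numeric(p), y, 0.5, 0.5, 1)
  set.seed(1203)
  mism <- character()
  iGR <- 12; iDR <- 13; iDRN <- 14; iCORT <- 10; iGRm <- 11
  for (i in seq_len(n_probe)) {
    y <- runif(14, 0, 5)
    dy <- rhs_fun(y)
    bind <- p["k_on"] * y[iCORT] * y[iGR]
    transl <- p["k_T"] * y[iDR]
    recyc <- p["r_f"] * p["k_re"] * y[iDRN]
    # reconstruct each equation's copy of the shared fluxes
    dGR_resid <- dy[iGR] - (p["k_syn_GR"] * y[iGRm] + recyc - bind -
                              p["k_deg_GR"] * y[iGR])
    dDR_resid <- dy[iDR] - (bind - transl)
    dDRN_resid <- dy[iDRN] - (transl - recyc)
    tol <- 1e-10 * max(1, bind, transl, recyc)
    if (abs(dGR_resid) > tol)
      mism <- c(mism, sprintf(
        "GR equation: binding/recycling flux mismatch (residual %.3g)",
        dGR_resid))
    if (abs(dDR_resid) > tol)
      mism <- c(mism, sprintf(
        "DR equation: binding or translocation flux mismatch (residual %.3g)",
        dDR_resid))
    if (abs(dDRN_resid) > tol)
      mism <- c(mism, sprintf(
        "DRN equation: translocation or recycling flux mismatch (residual %.3g)",
        dDRN_resid))
  }
  mism <- unique(mism)
  structure(list(balanced = length(mism) == 0, mismatches = mism),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  if (x$balanced) cat("Receptor flux audit: balanced\n")
  else {
    cat("Receptor flux audit: MISMATCH\n")
    for (m in x$mismatches) cat(" -", m, "\n")
  }
  invisible(x)
}
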