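#' @useDynLib hpaclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm lm.fit coef vcov median sd quantile qnorm rnorm runif
#'   cor approx setNames
#' @importFrom utils head tail modifyList write.csv
#' @importFrom grDevices chull
NULL

.param_names <- c(
  "k_p1", "K_p1", "k_p2", "K_p2", "k_p3",
  "V_d1", "K_d1", "V_d2", "K_d2", "V_d3", "K_d3",
  "k_syn_GRm", "IC50_GRm", "k_deg",
  "k_syn_GR", "k_deg_GR",
  "k_on", "k_T", "k_re", "r_f",
  "k_t", "k_us", "K_M_us", "n", "k_deg_us", "k_eff"
)

.state_names <- c(
  "light_TCsynth_1", "light_TCsynth_2", "light_TCsynth_3",
  "light_TCdeg_1", "light_TCdeg_2", "light_TCdeg_3",
  "light_effect",
  "CRH", "ACTH", "CORT", "GR_mRNA", "GR", "DR", "DRN"
)

#' Model parameters for the light-entrained HPA axis oscillator
#'
#' Constructs and validates the full parameter set of the coupled
#' photic-input / HPA / glucocorticoid-receptor ODE system.  Values not
#' supplied default to the repository defaults in
#' [default_parameters()].  All rates are per hour, concentrations in
#' arbitrary units.
#'
#' The three regulatory parameters studied throughout the package are
#' `K_p1` (hypothalamic feedback inhibition constant), `K_p2` (pituitary
#' feedback inhibition constant) and `k_p3` (adrenal sensitivity);
#' `k_p1` is the zero-order CRH synthesis rate representing central
#' hypothalamic drive, elevated to simulate chronic stress.
#'
#' @param ... named parameter overrides (see [default_parameters()] for
#'   the complete list of names).
#' @param base parameter object or named list/vector to start from.
#' @return an object of class `hpa_parameters` (a named numeric vector).
#' @examples
#' p <- hpa_parameters(k_p3 = 1.2)
#' p["k_p3"]
#' @export
hpa_parameters <- function(..., base = default_parameters()) {
  p <- unclass(base)[.param_names]
  args <- list(...)
  over <- setNames(vapply(args, function(v) as.numeric(v)[1], numeric(1)),
                   names(args))
  if (length(over)) {
    bad <- setdiff(names(over), .param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p <- setNames(as.numeric(p), .param_names)
  validate_parameters(p)
  structure(p, class = "hpa_parameters")
}

validate_parameters <- function(p) {
  if (anyNA(p) || any(!is.finite(p)))
    stop("all parameters must be finite")
  if (any(p <= 0 & names(p) != "r_f"))
    stop("all parameters must be strictly positive (r_f may be 0): ",
         paste(names(p)[p <= 0 & names(p) != "r_f"], collapse = ", "))
  if (p["r_f"] < 0 || p["r_f"] > 1) stop("r_f must lie in [0, 1]")
  if (p["n"] < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

#' Repository default parameter values
#'
#' The default rate and affinity constants of the model.  They were chosen
#' so that the entrained system oscillates with a 24 h period under the
#' 14 h light : 10 h dark schedule, with a free-running period of about
#' 24.3 h in constant darkness and a clear-amplitude corticosterone
#' rhythm.  They are repository defaults, not experimentally fitted
#' values.
#'
#' @return an `hpa_parameters` object.
#' @export
default_parameters <- function() {
  structure(setNames(c(
    3.0, 0.3, 1.0, 0.4, 1.0,            # k_p1 K_p1 k_p2 K_p2 k_p3
    1.5, 0.05, 1.0, 0.05, 0.9, 0.05,    # V_d/K_d for CRH, ACTH, CORT
    1.0, 0.4, 0.12,                     # GR mRNA synth / IC50 / deg
    0.8, 0.1,                           # GR protein synth / deg
    0.05, 0.8, 0.8, 0.5,                # k_on k_T k_re r_f
    2.0, 3.0, 0.6, 5.0, 1.0, 2.0        # photic: k_t k_us K_M_us n k_deg_us k_eff
  ), .param_names), class = "hpa_parameters")
}

#' @export
print.hpa_parameters <- function(x, ...) {
  cat("HPA axis model parameters (rates per hour)\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Default initial state
#'
#' Small positive constants for the hormonal/receptor variables and zeros
#' for the photic cascade.
#'
#' @return named numeric vector of length 14.
#' @export
default_state <- function() {
  setNames(c(rep(0, 7), rep(0.1, 7)), .state_names)
}

#' Read / write model configuration as YAML
#'
#' A flat mapping of all parameter fields, with the light schedule
#' serialized alongside under `schedule:`.
#'
#' @param path file path.
#' @param params `hpa_parameters`.
#' @param schedule `light_schedule`.
#' @return `read_model_config()` returns `list(params, schedule)`.
#' @examples
#' cfg <- read_model_config(system.file("extdata", "default_model.yaml",
#'                                      package = "hpaclock"))
#' cfg$schedule
#' @export
write_model_config <- function(path, params = default_parameters(),
                               schedule = light_schedule()) {
  cfg <- list(parameters = as.list(setNames(as.numeric(params),
                                            names(unclass(params)))),
              schedule = list(lights_on = schedule$lights_on,
                              lights_off = schedule$lights_off,
                              period = schedule$period,
                              amplitude = schedule$amplitude,
                              light_deg_signal = schedule$light_deg_signal))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- do.call(hpa_parameters, cfg$parameters)
  s <- cfg$schedule
  sched <- light_schedule(lights_on = s$lights_on, lights_off = s$lights_off,
                          period = s$period,
                          amplitude = if (is.null(s$amplitude)) 1 else s$amplitude,
                          light_deg_signal = if (is.null(s$light_deg_signal))
                            "dark" else s$light_deg_signal)
  list(params = p, schedule = sched)
}
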