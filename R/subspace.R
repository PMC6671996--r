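#' Chronic stress conditions
#'
#' A stress condition is the label and value of the zero-order CRH
#' synthesis rate `k_p1` (central hypothalamic drive).  Chronic stress is
#' simulated by persistently elevating `k_p1`; the defaults are 2x and 4x
#' the nominal drive for the intermediate and high conditions.
#'
#' @param label one of `"nominal"`, `"intermediate"`, `"high"`.
#' @param k_p1_value the CRH synthesis rate (conc/h).
#' @return object of class `stress_condition`.
#' @export
stress_condition <- function(label = c("nominal", "intermediate", "high"),
                             k_p1_value) {
  label <- match.arg(label)
  stopifnot(k_p1_value > 0)
  structure(list(label = label, k_p1_value = k_p1_value),
            class = "stress_condition")
}

#' @rdname stress_condition
#' @param base_k_p1 nominal drive (defaults to the repository default
#'   `k_p1`).
#' @param multipliers fold-elevations for (nominal, intermediate, high);
#'   must be strictly increasing.
#' @return `stress_conditions()`: named list of the three conditions.
#' @export
stress_conditions <- function(base_k_p1 = default_parameters()[["k_p1"]],
                              multipliers = c(1, 2, 4)) {
  if (any(diff(multipliers) <= 0))
    stop("stress multipliers must be strictly increasing ",
         "(nominal < intermediate < high)")
  labs <- c("nominal", "intermediate", "high")
  setNames(lapply(1:3, function(i)
    stress_condition(labs[i], base_k_p1 * multipliers[i])), labs)
}

#' Default regulatory sampling box
#'
#' Bounds of the log-uniform search box over the three regulatory
#' parameters.  The box spans the hypothalamic and pituitary feedback
#' constants and the adrenal sensitivity widely enough to contain the
#' calibrated subspaces of the nominal and both chronically stressed
#' conditions.
#'
#' @return 3 x 2 matrix with rownames K_p1, K_p2, k_p3.
#' @export
default_sampling_box <- function() {
  matrix(c(0.015, 0.6,
           0.15,  1.6,
           0.5,   2.2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("K_p1", "K_p2", "k_p3"), c("lower", "upper")))
}

#' Sample the calibrated regulatory subspace
#'
#' Draws `n_samples` triples (K_p1, K_p2, k_p3) from the search box
#' (log-uniform Latin hypercube by default), simulates each to the
#' entrained limit cycle under the given stress condition, fits a cosinor
#' to the steady-state CORT profile, and retains the triples whose
#' cosinor parameters pass the calibration target.
#'
#' @param condition [stress_condition()].
#' @param target [calibration_target()].
#' @param box 3 x 2 bounds matrix (see [default_sampling_box()]).
#' @param n_samples number of candidate triples.
#' @param seed integer RNG seed (reproducible given identical config).
#' @param params base [hpa_parameters()]; `k_p1` is replaced by the
#'   condition value and the triple replaces (K_p1, K_p2, k_p3).
#' @param schedule [light_schedule()].
#' @param sampler `"lhs"` (Latin hypercube) or `"uniform"`.
#' @param transient_days,tol,max_days,dt,rtol,atol limit-cycle controls
#'   (moderate solver tolerances by default; candidate screening does not
#'   need the tight trajectory-analysis tolerances).
#' @param prefilter_sd early-rejection threshold: candidates whose first
#'   post-transient cycle deviates from the target by more than this many
#'   target SDs on any cosinor parameter are rejected without running the
#'   full convergence loop (`Inf` disables the shortcut).
#' @return object of class `accepted_subspace`: list with `samples`
#'   (data.frame of all candidates with cosinor fits and `accepted`
#'   flag), `triples` (accepted subset), `condition`, `target`, `box`,
#'   `seed`.  If no candidate passes, the object is returned with zero
#'   accepted rows and a warning reporting the nearest misses.
#' @export
sample_subspace <- function(condition, target, box = default_sampling_box(),
                            n_samples = 2000, seed = 1,
                            params = default_parameters(),
                            schedule = light_schedule(),
                            sampler = c("lhs", "uniform"),
                            transient_days = 8, tol = 1e-3, max_days = 20,
                            dt = 0.1, rtol = 1e-5, atol = 1e-7,
                            prefilter_sd = 6) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(condition, "stress_condition"),
            inherits(target, "calibration_target"),
            all(box > 0), n_samples >= 0)
  set.seed(seed)
  u <- if (n_samples == 0) matrix(numeric(0), 0, 3)
  else if (sampler == "lhs") lhs::randomLHS(n_samples, 3)
  else matrix(runif(3 * n_samples), ncol = 3)
  lo <- log(box[, 1]); hi <- log(box[, 2])
  triples <- exp(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  colnames(triples) <- rownames(box)

  res <- data.frame(K_p1 = numeric(0), K_p2 = numeric(0),
                    k_p3 = numeric(0), mesor = numeric(0),
                    amplitude = numeric(0), acrophase = numeric(0),
                    converged = logical(0), accepted = logical(0))
  if (n_samples > 0)
    res <- data.frame(K_p1 = triples[, "K_p1"], K_p2 = triples[, "K_p2"],
                      k_p3 = triples[, "k_p3"], mesor = NA_real_,
                      amplitude = NA_real_, acrophase = NA_real_,
                      converged = FALSE, accepted = FALSE)
  for (i in seq_len(nrow(res))) {
    p <- hpa_parameters(k_p1 = condition$k_p1_value, K_p1 = res$K_p1[i],
                        K_p2 = res$K_p2[i], k_p3 = res$k_p3[i],
                        base = params)
    sc <- tryCatch(
      .screen_candidate(p, schedule, target, transient_days, tol, max_days,
                        dt, rtol, atol, prefilter_sd = prefilter_sd),
      error = function(e) NULL)
    if (is.null(sc)) next
    res$mesor[i] <- sc$fit$mesor
    res$amplitude[i] <- sc$fit$amplitude
    res$acrophase[i] <- sc$fit$acrophase
    res$converged[i] <- sc$converged
    res$accepted[i] <- sc$converged && passes_calibration(sc$fit, target)
  }
  res <- res[!duplicated(res[, c("K_p1", "K_p2", "k_p3")]), ]
  acc <- res[res$accepted, , drop = FALSE]
  if (nrow(acc) == 0) {
    dev <- with(res, pmax(abs(mesor - target$mesor) / target$sd["mesor"],
                          abs(amplitude - target$amplitude) /
                            target$sd["amplitude"],
                          circular_diff(acrophase, target$acrophase,
                                        target$period) /
                            target$sd["acrophase"]))
    near <- res[order(dev), ][seq_len(min(3, nrow(res))), ]
    warning("empty subspace: no candidate passed calibration; nearest ",
            "misses at max standardized deviation ",
            paste(signif(sort(dev)[seq_len(min(3, length(dev)))], 3),
                  collapse = ", "))
    attr(res, "nearest_misses") <- near
  }
  structure(list(samples = res, triples = acc, condition = condition,
                 target = target, box = box, seed = seed),
            class = "accepted_subspace")
}

# Candidate screening: one transient burn, an early rejection when the
# first steady-ish cycle is far outside the acceptance band (more than
# prefilter_sd target SDs on any cosinor parameter; by then the dominant
# transient mode has decayed to below a percent, so candidates near the
# band are never discarded), then cycle-to-cycle convergence as in
# integrate_to_limit_cycle.
.screen_candidate <- function(p, schedule, target, transient_days, tol,
                              max_days, dt, rtol, atol, prefilter_sd = 6) {
  period <- schedule$period
  tr <- integrate_hpa(p, schedule, 0, transient_days * period,
                      dt = period / 2, rtol = rtol, atol = atol)
  y <- tr$states[nrow(tr$states), ]
  t_cur <- transient_days * period
  cyc <- integrate_hpa(p, schedule, t_cur, t_cur + period, dt = dt, y0 = y,
                       rtol = rtol, atol = atol)
  cf <- fit_cosinor(cyc$times, cyc$states[, "CORT"], period = period)
  dev <- max(abs(cf$mesor - target$mesor) / target$sd["mesor"],
             abs(cf$amplitude - target$amplitude) / target$sd["amplitude"],
             circular_diff(cf$acrophase, target$acrophase, period) /
               target$sd["acrophase"])
  if (is.finite(prefilter_sd) && dev > prefilter_sd)
    return(list(fit = cf, converged = FALSE))
  prev <- cyc$states[, "CORT"]
  day <- transient_days + 1
  repeat {
    y <- cyc$states[nrow(cyc$states), ]
    t_cur <- t_cur + period
    cyc <- integrate_hpa(p, schedule, t_cur, t_cur + period, dt = dt,
                         y0 = y, rtol = rtol, atol = atol)
    cort <- cyc$states[, "CORT"]
    amp <- (max(cort) - min(cort)) / 2
    resid <- if (amp > 0) max(abs(cort - prev)) / amp else max(abs(cort - prev))
    day <- day + 1
    if (resid < tol) {
      cf <- fit_cosinor(cyc$times, cort, period = period)
      return(list(fit = cf, converged = TRUE))
    }
    if (day >= max_days)
      return(list(fit = fit_cosinor(cyc$times, cort, period = period),
                  converged = FALSE))
    prev <- cort
  }
}

#' @export
print.accepted_subspace <- function(x, ...) {
  cat(sprintf(
    "Accepted regulatory subspace [%s, k_p1 = %.3g]: %d / %d accepted\n",
    x$condition$label, x$condition$k_p1_value, nrow(x$triples),
    nrow(x$samples)))
  invisible(x)
}

#' Surface area of an accepted subspace
#'
#' The accepted triples form (approximately) a 2-manifold
#' `k_p3 = f(K_p1, K_p2)`.  The area is computed by Delaunay
#' triangulation of the accepted points in the (K_p1, K_p2) plane,
#' restricted to the region's alpha complex (circumradius at most
#' `alpha`, default twice the median nearest-neighbour spacing), lifted
#' to 3D through each triple's k_p3, summing 3D triangle areas.
#'
#' For an `accepted_subspace` the axes are first normalized by the
#' sampling-box widths, so the area is reported in box units (arbitrary
#' units): the raw parameters carry different physical units and
#' extents, and a Euclidean surface area is only meaningful on a common
#' scale.  By default (`lift = "projected"`) the area is the footprint
#' of the accepted region in the normalized feedback plane — the
#' accepted set has a finite acceptance-band thickness, and at the
#' accepted-point densities the sampling achieves, sample-to-sample
#' k_p3 jitter within that thickness inflates a 3D-lifted area
#' erratically, whereas the footprint is stable; `lift = "k_p3"`
#' requests the 3D area of the lifted surface instead.  A plain
#' data.frame input is always measured as the 3D lifted surface in its
#' raw coordinates.
#'
#' @param sub `accepted_subspace`, or a data.frame with columns K_p1,
#'   K_p2, k_p3.
#' @param alpha alpha-complex radius (`NULL` for automatic).
#' @param lift `"projected"` (default) or `"k_p3"`; only used for
#'   `accepted_subspace` input.
#' @return area (arbitrary units).
#' @export
surface_area <- function(sub, alpha = NULL, lift = c("projected", "k_p3")) {
  lift <- match.arg(lift)
  if (inherits(sub, "accepted_subspace")) {
    tr <- sub$triples
    if (nrow(tr) < 3)
      stop("degenerate geometry: fewer than 3 accepted triples")
    w <- sub$box[, 2] - sub$box[, 1]
    z <- if (lift == "projected") rep(0, nrow(tr)) else tr$k_p3 / w[3]
    return(lifted_surface_area(tr$K_p1 / w[1], tr$K_p2 / w[2], z, alpha))
  }
  tr <- sub
  if (nrow(tr) < 3) stop("degenerate geometry: fewer than 3 accepted triples")
  lifted_surface_area(tr$K_p1, tr$K_p2, tr$k_p3, alpha)
}

#' Test whether a triple lies inside the accepted region
#'
#' For an `accepted_subspace`, a query triple counts as contained when
#' either (a) its (K_p1, K_p2) projection lies inside the convex hull of
#' the accepted projections, or (b) its box-normalized 3D distance to
#' the nearest accepted triple does not exceed twice the accepted set's
#' median nearest-neighbour spacing — i.e. the accepted region covers
#' the triple at the resolution the sampling achieved.  For a plain
#' data.frame only the hull test is applied.  Used for
#' parameter-recovery checks against synthetic targets.
#'
#' @param sub `accepted_subspace` (or data.frame with K_p1, K_p2
#'   columns).
#' @param triple named vector/list with K_p1, K_p2 (and k_p3 for the
#'   resolution test).
#' @return logical.
#' @export
subspace_contains <- function(sub, triple) {
  tr <- if (inherits(sub, "accepted_subspace")) sub$triples else sub
  if (nrow(tr) < 3) return(FALSE)
  if (inherits(sub, "accepted_subspace") && !is.null(triple[["k_p3"]])) {
    w <- sub$box[, 2] - sub$box[, 1]
    P <- cbind(tr$K_p1 / w[1], tr$K_p2 / w[2], tr$k_p3 / w[3])
    q <- c(triple[["K_p1"]] / w[1], triple[["K_p2"]] / w[2],
           triple[["k_p3"]] / w[3])
    d <- sqrt(rowSums(sweep(P, 2, q)^2))
    D <- as.matrix(stats::dist(P)); diag(D) <- Inf
    if (min(d) <= 2 * median(apply(D, 1, min))) return(TRUE)
  }
  x <- tr$K_p1; y <- tr$K_p2
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  qx <- as.numeric(triple[["K_p1"]]); qy <- as.numeric(triple[["K_p2"]])
  n <- length(hx)
  # point-in-convex-polygon: consistent orientation of all edge cross
  # products (boundary counts as inside)
  s <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (hx[j] - hx[i]) * (qy - hy[i]) - (hy[j] - hy[i]) * (qx - hx[i])
  }, numeric(1))
  all(s <= 1e-12) || all(s >= -1e-12)
}

#' Compare calibrated subspaces across stress conditions
#'
#' Summarizes each condition's accepted triples (parameter means and
#' ranges, surface area) and reports the qualitative orderings: mean
#' hypothalamic feedback constant K_p1 decreasing with stress, mean
#' adrenal sensitivity k_p3 increasing, and surface area decreasing.
#'
#' @param nominal,intermediate,high `accepted_subspace` objects.
#' @return object of class `subspace_comparison`: list with `summary`
#'   (data.frame) and `trends` (named logicals).
#' @export
compare_conditions <- function(nominal, intermediate, high) {
  subs <- list(nominal = nominal, intermediate = intermediate, high = high)
  for (s in subs)
    if (nrow(s$triples) == 0)
      stop("empty subspace for condition ", s$condition$label)
  summ <- do.call(rbind, lapply(subs, function(s) {
    tr <- s$triples
    data.frame(condition = s$condition$label,
               k_p1 = s$condition$k_p1_value, n_accepted = nrow(tr),
               mean_K_p1 = mean(tr$K_p1), mean_K_p2 = mean(tr$K_p2),
               mean_k_p3 = mean(tr$k_p3),
               min_K_p1 = min(tr$K_p1), max_K_p1 = max(tr$K_p1),
               area = if (nrow(tr) >= 3) surface_area(s) else NA_real_)
  }))
  rownames(summ) <- NULL
  trends <- c(
    K_p1_decreases = summ$mean_K_p1[1] > summ$mean_K_p1[2] &&
      summ$mean_K_p1[2] > summ$mean_K_p1[3],
    k_p3_increases = summ$mean_k_p3[1] < summ$mean_k_p3[2] &&
      summ$mean_k_p3[1] < summ$mean_k_p3[3],
    area_decreases = !anyNA(summ$area) && summ$area[1] > summ$area[2] &&
      summ$area[2] > summ$area[3])
  structure(list(summary = summ, trends = trends),
            class = "subspace_comparison")
}

#' @export
print.subspace_comparison <- function(x, ...) {
  print(x$summary, digits = 4)
  cat("Trends:",
      paste(names(x$trends), ifelse(x$trends, "yes", "no"), sep = ": ",
            collapse = "; "), "\n")
  invisible(x)
}

#' Write a subspace sample table as CSV
#'
#' One row per candidate with the triple, cosinor fit and accepted flag.
#'
#' @param sub `accepted_subspace`.
#' @param path file path.
#' @export
write_subspace_csv <- function(sub, path) {
  df <- sub$samples
  df$condition <- sub$condition$label
  df$k_p1 <- sub$condition$k_p1_value
  df$seed <- sub$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
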