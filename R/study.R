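#' Select representative triples from an accepted subspace
#'
#' Picks `per_level` triples at each of `n_levels` adrenal-sensitivity
#' (k_p3) quantile levels: the accepted triples nearest each k_p3
#' quantile are pooled and, within a level, the triples spanning the
#' K_p1 extent (minimum, median, maximum) are chosen.  This mirrors the
#' selection of representative parameter sets in sets of approximately
#' constant adrenal sensitivity spanning the regulatory surface.
#'
#' @param sub `accepted_subspace` (or data.frame with columns K_p1,
#'   K_p2, k_p3).
#' @param n_levels number of k_p3 levels (default 3).
#' @param per_level triples per level (default 3).
#' @param level_quantiles k_p3 quantiles defining the levels.
#' @return data.frame of `n_levels * per_level` triples with a `level`
#'   column (1 = lowest k_p3).
#' @export
select_representative_triples <- function(sub, n_levels = 3,
                                          per_level = 3,
                                          level_quantiles = c(0.1, 0.5,
                                                              0.9)) {
  tr <- if (inherits(sub, "accepted_subspace")) sub$triples else sub
  tr <- tr[!duplicated(tr[, c("K_p1", "K_p2", "k_p3")]), , drop = FALSE]
  if (nrow(tr) < n_levels * per_level)
    stop("insufficient accepted triples (", nrow(tr), ") for ",
         n_levels * per_level, " representatives")
  stopifnot(length(level_quantiles) == n_levels)
  qs <- quantile(tr$k_p3, level_quantiles, names = FALSE)
  used <- integer(0)
  out <- NULL
  for (lv in seq_len(n_levels)) {
    avail <- setdiff(seq_len(nrow(tr)), used)
    near <- avail[order(abs(tr$k_p3[avail] - qs[lv]))]
    pool <- near[seq_len(min(max(per_level * 4, per_level), length(near)))]
    pool <- pool[order(tr$K_p1[pool])]
    pick <- pool[unique(round(seq(1, length(pool),
                                  length.out = per_level)))]
    # pad in the rare case rounding collapses picks
    extra <- setdiff(pool, pick)
    while (length(pick) < per_level && length(extra) > 0) {
      pick <- c(pick, extra[1]); extra <- extra[-1]
    }
    used <- c(used, pick)
    sel <- tr[pick, , drop = FALSE]
    sel$level <- lv
    out <- rbind(out, sel)
  }
  rownames(out) <- NULL
  out
}

# representative triples when the subspace is large enough, otherwise all
# accepted triples (sparse stressed subspaces at reduced sample counts)
.representatives_or_all <- function(sub, per_level = 3, n_levels = 3) {
  tr <- sub$triples
  if (nrow(tr) >= n_levels * per_level) {
    reps <- select_representative_triples(sub, n_levels = n_levels,
                                          per_level = per_level)
  } else {
    reps <- tr[order(tr$k_p3), , drop = FALSE]
    if (nrow(reps) == 0) stop("empty subspace for condition ",
                              sub$condition$label)
    reps$level <- as.integer(cut(seq_len(nrow(reps)), breaks = n_levels,
                                 labels = FALSE))
  }
  reps
}

#' Run the full in-silico study
#'
#' End-to-end orchestration: generate the synthetic calibration target,
#' sample the calibrated regulatory subspaces under the nominal,
#' intermediate and high chronic-stress conditions, compare them
#' (parameter shifts and surface areas), score the acute stress response
#' on representative triples with symbolic partitioning, run the
#' shift-work and jet-lag photoperiod protocols, compute Arnold tongues
#' for representative triples and the Floquet exponents with the
#' regression on the regulatory parameters.
#'
#' Stage sizes are configurable so the study scales from a smoke test to
#' a full reproduction.  All randomness derives from `seed`.
#'
#' @param seed integer seed.
#' @param n_samples candidates per condition.
#' @param spec [synthetic_target_spec()] (its seed is replaced by
#'   `seed`).
#' @param multipliers chronic stress fold-elevations of k_p1.
#' @param tongue_per_level representative triples per k_p3 level (3
#'   levels) used for the tongue analysis of each condition.
#' @param period_grid,strength_grid tongue grids.
#' @param protocol_triples number of accepted triples (spread over k_p3)
#'   used for the inversion/resynchronization protocols.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose print stage progress.
#' @return list with components `target`, `subspaces`, `comparison`,
#'   `acute`, `symbols`, `protocols`, `tongues`, `floquet`,
#'   `regression`, `trends`, `seed`.
#' @export
run_study <- function(seed = 1, n_samples = 600,
                      spec = synthetic_target_spec(),
                      multipliers = c(1, 2, 4),
                      tongue_per_level = 1,
                      period_grid = seq(18, 33, by = 1),
                      strength_grid = c(0.25, 0.5, 0.75, 1),
                      protocol_triples = 6, out_dir = NULL,
                      verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (any(diff(multipliers) <= 0))
    stop("stress multipliers must be strictly increasing")
  spec$seed <- seed
  say("[1/6] synthetic calibration target")
  target <- make_calibration_target(spec)
  conds <- stress_conditions(base_k_p1 = spec$params[["k_p1"]],
                             multipliers = multipliers)
  say("[2/6] subspace sampling (%d candidates x 3 conditions)", n_samples)
  subspaces <- lapply(conds, function(cd)
    sample_subspace(cd, target, box = spec$box, n_samples = n_samples,
                    seed = seed + match(cd$label, names(conds)),
                    params = spec$params))
  comparison <- compare_conditions(subspaces$nominal,
                                   subspaces$intermediate, subspaces$high)
  say("[3/6] acute stress responses")
  acute <- NULL
  for (lab in names(subspaces)) {
    reps <- .representatives_or_all(subspaces[[lab]], per_level = 3)
    for (i in seq_len(nrow(reps))) {
      p <- hpa_parameters(k_p1 = conds[[lab]]$k_p1_value,
                          K_p1 = reps$K_p1[i], K_p2 = reps$K_p2[i],
                          k_p3 = reps$k_p3[i], base = spec$params)
      cycp <- integrate_to_limit_cycle(p, light_schedule(),
                                       transient_days = 8, tol = 1e-3,
                                       max_days = 40, dt = 0.05,
                                       rtol = 1e-6, atol = 1e-8)
      d <- acute_stress_response(
        p, acute_stressor(onset = mid_inactive_onset(cycp)), cycle = cycp)
      acute <- rbind(acute, data.frame(condition = lab, level = reps$level[i],
                                       K_p1 = reps$K_p1[i],
                                       K_p2 = reps$K_p2[i],
                                       k_p3 = reps$k_p3[i], delta_auc = d))
    }
  }
  symbols <- cbind(acute, symbolize(acute$delta_auc)[c("z", "symbol")])
  say("[4/6] photoperiod perturbation protocols")
  reps_nom <- .representatives_or_all(subspaces$nominal,
                                      per_level = ceiling(protocol_triples / 3))
  reps_nom <- reps_nom[order(reps_nom$k_p3), , drop = FALSE]
  if (nrow(reps_nom) > protocol_triples)
    reps_nom <- reps_nom[unique(round(seq(1, nrow(reps_nom),
                                          length.out = protocol_triples))), ]
  protocols <- NULL
  for (i in seq_len(nrow(reps_nom))) {
    p <- hpa_parameters(k_p1 = conds$nominal$k_p1_value,
                        K_p1 = reps_nom$K_p1[i], K_p2 = reps_nom$K_p2[i],
                        k_p3 = reps_nom$k_p3[i], base = spec$params)
    cyc <- integrate_to_limit_cycle(p, light_schedule(),
                                    transient_days = 8, tol = 1e-3,
                                    max_days = 40, dt = 0.05,
                                    rtol = 1e-6, atol = 1e-8)
    shift <- tryCatch(
      transient_inversion_phase_shift(p, cycle = cyc, follow_days = 15),
      error = function(e) NA_real_)
    resync <- tryCatch(
      resynchronization_time(p, cycle = cyc),
      error = function(e) NA_real_)
    protocols <- rbind(protocols,
                       data.frame(K_p1 = reps_nom$K_p1[i],
                                  K_p2 = reps_nom$K_p2[i],
                                  k_p3 = reps_nom$k_p3[i],
                                  max_phase_shift = shift,
                                  resync_days = resync))
  }
  say("[5/6] Arnold tongues (%d x %d grid)", length(period_grid),
      length(strength_grid))
  tongues <- NULL
  for (lab in names(subspaces)) {
    reps <- .representatives_or_all(subspaces[[lab]],
                                    per_level = tongue_per_level)
    for (i in seq_len(nrow(reps))) {
      p <- hpa_parameters(k_p1 = conds[[lab]]$k_p1_value,
                          K_p1 = reps$K_p1[i], K_p2 = reps$K_p2[i],
                          k_p3 = reps$k_p3[i], base = spec$params)
      tg <- arnold_tongue(p, period_grid, strength_grid)
      tongues <- rbind(tongues,
                       data.frame(condition = lab, level = reps$level[i],
                                  K_p1 = reps$K_p1[i], K_p2 = reps$K_p2[i],
                                  k_p3 = reps$k_p3[i],
                                  tau = tg$tau, A0 = tg$A0,
                                  tongue_area = tongue_area(tg)))
    }
  }
  say("[6/6] Floquet exponents and regression")
  # intrinsic (constant-darkness) amplitude-relaxation rate: the quantity
  # the entrainment-range theory relates to tongue width
  floq <- NULL
  reps <- .representatives_or_all(subspaces$nominal, per_level = 3)
  for (i in seq_len(nrow(reps))) {
    p <- hpa_parameters(k_p1 = conds$nominal$k_p1_value,
                        K_p1 = reps$K_p1[i], K_p2 = reps$K_p2[i],
                        k_p3 = reps$k_p3[i], base = spec$params)
    fr <- floquet_exponents(p, constant_darkness(), transient_days = 30,
                            tol = 1e-4, rtol = 1e-9, atol = 1e-11)
    floq <- rbind(floq, data.frame(K_p1 = reps$K_p1[i],
                                   K_p2 = reps$K_p2[i],
                                   k_p3 = reps$k_p3[i],
                                   leading_exponent = fr$leading_exponent))
  }
  regression <- regress_exponent_on_params(floq)

  trends <- c(comparison$trends,
              acute_k_p3_positive = with(symbols, cor(k_p3, delta_auc,
                                                      method = "spearman"))
              > 0)
  res <- list(target = target, subspaces = subspaces,
              comparison = comparison, acute = acute, symbols = symbols,
              protocols = protocols, tongues = tongues, floquet = floq,
              regression = regression, trends = trends, seed = seed)
  if (!is.null(out_dir)) .write_study_outputs(res, out_dir)
  res
}

.write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(res$subspaces))
    write_subspace_csv(res$subspaces[[lab]],
                       file.path(out_dir, paste0("subspace_", lab, ".csv")))
  write.csv(res$symbols, file.path(out_dir, "acute_response.csv"),
            row.names = FALSE)
  write.csv(res$protocols, file.path(out_dir, "photoperiod_protocols.csv"),
            row.names = FALSE)
  write.csv(res$tongues, file.path(out_dir, "tongue_areas.csv"),
            row.names = FALSE)
  write.csv(res$floquet, file.path(out_dir, "floquet.csv"),
            row.names = FALSE)
  summary <- list(seed = res$seed,
                  package_version =
                    as.character(utils::packageVersion("hpaclock")),
                  subspace_summary = res$comparison$summary,
                  regression = as.list(res$regression$coefficients),
                  r_squared = res$regression$r_squared,
                  trends = as.list(res$trends))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
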