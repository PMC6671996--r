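# A small shared sampling run keeps these tests fast; statistical
# behaviour at scale is exercised by the acceptance suite.
spec <- synthetic_target_spec(seed = 3)
target <- make_calibration_target(spec)
conds <- stress_conditions()

test_that("condition constructor enforces the stress ordering", {
  expect_error(stress_conditions(multipliers = c(1, 4, 2)), "increasing")
  cs <- stress_conditions(base_k_p1 = 3)
  expect_equal(cs$intermediate$k_p1_value, 6)
  expect_equal(cs$high$k_p1_value, 12)
})

test_that("sampling is deterministic given a seed and records fits", {
  # small draws may legitimately find no passer; the warning is expected
  s1 <- suppressWarnings(
    sample_subspace(conds$nominal, target, n_samples = 40, seed = 9))
  s2 <- suppressWarnings(
    sample_subspace(conds$nominal, target, n_samples = 40, seed = 9))
  expect_identical(s1$samples, s2$samples)
  s3 <- suppressWarnings(
    sample_subspace(conds$nominal, target, n_samples = 40, seed = 10))
  expect_false(identical(s1$samples$K_p1, s3$samples$K_p1))
  # every candidate lies inside the box
  box <- default_sampling_box()
  expect_true(all(s1$samples$K_p1 >= box[1, 1] &
                    s1$samples$K_p1 <= box[1, 2]))
  # converged candidates carry cosinor fits
  conv <- s1$samples[s1$samples$converged, ]
  expect_true(all(is.finite(conv$mesor)))
  # accepted triples all pass the target
  if (nrow(s1$triples) > 0)
    expect_true(all(vapply(seq_len(nrow(s1$triples)), function(i)
      passes_calibration(list(mesor = s1$triples$mesor[i],
                              amplitude = s1$triples$amplitude[i],
                              acrophase = s1$triples$acrophase[i]),
                         target), logical(1))))
})

test_that("an empty draw list yields an empty subspace with a warning", {
  expect_warning(s0 <- sample_subspace(conds$nominal, target,
                                       n_samples = 0, seed = 1),
                 "empty subspace")
  expect_equal(nrow(s0$triples), 0)
})

test_that("acceptance regions are nested as the target SDs shrink", {
  # reuse one converged sample table; acceptance at half the SD must be a
  # subset of acceptance at the full SD, for several shrink factors
  s1 <- suppressWarnings(
    sample_subspace(conds$nominal, target, n_samples = 60, seed = 21))
  conv <- s1$samples[s1$samples$converged, ]
  accept_at <- function(f) {
    tgt <- calibration_target(target$mesor, target$amplitude,
                              target$acrophase,
                              f * target$sd["mesor"],
                              f * target$sd["amplitude"],
                              f * target$sd["acrophase"])
    which(vapply(seq_len(nrow(conv)), function(i)
      passes_calibration(list(mesor = conv$mesor[i],
                              amplitude = conv$amplitude[i],
                              acrophase = conv$acrophase[i]), tgt),
      logical(1)))
  }
  sets <- lapply(c(2, 1, 0.5, 0.25), accept_at)
  for (k in 2:length(sets))
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("subspace comparison reports identity deltas for equal inputs", {
  tr <- data.frame(K_p1 = c(0.2, 0.3, 0.25, 0.28),
                   K_p2 = c(0.4, 0.5, 0.6, 0.45),
                   k_p3 = c(1, 1.2, 1.1, 1.05))
  fake <- function(lab, kp1) structure(
    list(samples = tr, triples = tr,
         condition = stress_condition(lab, kp1),
         target = target, box = default_sampling_box(), seed = 1),
    class = "accepted_subspace")
  cmp <- compare_conditions(fake("nominal", 3), fake("intermediate", 6),
                            fake("high", 12))
  expect_equal(cmp$summary$mean_K_p1, rep(mean(tr$K_p1), 3))
  expect_equal(cmp$summary$area[1], cmp$summary$area[2])
  expect_false(cmp$trends[["K_p1_decreases"]])
  # constructed means are reported exactly
  expect_equal(cmp$summary$mean_k_p3[1], mean(tr$k_p3))
})

test_that("subspace CSV export carries condition metadata", {
  s1 <- suppressWarnings(
    sample_subspace(conds$nominal, target, n_samples = 10, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_subspace_csv(s1, path)
  df <- read.csv(path)
  expect_true(all(c("K_p1", "mesor", "accepted", "condition",
                    "seed") %in% names(df)))
  expect_equal(unique(df$condition), "nominal")
  unlink(path)
})
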