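# Dose recommendation, safety stopping, and the sequential trial loop.

robust_cfg <- function(...) {
  design_config(default_skeletons(),
                target_profile = c(0.49, 0.18, 0.23, 0.10), ...)
}

test_that("recommendation targets the closest dose with no-skip escalation", {
  th <- 0.47 / 1.5
  expect_equal(recommend_dose(c(0.10, 0.30, 0.50), th, current_dose = 2), 2L)
  # tie between doses 3 and 4 resolves low; no-skip caps the move at 2
  expect_equal(recommend_dose(c(0.05, 0.10, 0.31, 0.32), 0.315,
                              current_dose = 1), 2L)
  expect_equal(recommend_dose(c(0.05, 0.10, 0.31, 0.32), 0.315,
                              current_dose = 3), 3L)
  # no escalation past the top dose
  expect_equal(recommend_dose(c(0.05, 0.10, 0.20), 0.9, current_dose = 3), 3L)
  # de-escalation may skip down
  expect_equal(recommend_dose(c(0.31, 0.6, 0.7, 0.8), 0.3,
                              current_dose = 4), 1L)
  # restriction off: jump straight to the candidate
  expect_equal(recommend_dose(c(0.05, 0.10, 0.31, 0.32), 0.315,
                              current_dose = 1,
                              escalation_restricted = FALSE), 3L)
  # restricted candidate set (final MTD call considers tried doses only)
  expect_equal(recommend_dose(c(0.05, 0.10, 0.31, 0.32), 0.315,
                              allowed = 1:2), 2L)
})

test_that("safety stop triggers on overwhelming low-dose toxicity only", {
  cfg <- robust_cfg()
  ens <- cfg$ensemble
  empty <- ensemble_posterior(ens, trial_data(6), cfg$target_norm)
  expect_false(check_stop(empty, cfg))
  # five consecutive grade-4 outcomes at dose 1
  toxic <- trial_data_from_scores(6, dose = rep(1, 5), y = rep(1, 5))
  ep <- ensemble_posterior(ens, toxic, cfg$target_norm)
  expect_true(check_stop(ep, cfg))
  # oracle confirmation under the selected model
  sel <- ep$selected
  oracle <- oracle_posterior(ens$models[[sel]]$skeleton, rep(1, 5),
                             rep(1, 5), target_norm = cfg$target_norm)
  expect_equal(ep$per_model[[sel]]$prob_overdose_d1,
               oracle$prob_overdose_d1, tolerance = 1e-6)
  expect_gt(oracle$prob_overdose_d1, 0.90)
  # a cutoff of 1 can never be exceeded
  cfg1 <- robust_cfg(stop_cutoff = 1)
  expect_false(check_stop(ep, cfg1))
})

test_that("an all-benign scenario escalates one level per cohort to the top", {
  safe <- scenario(matrix(rep(c(1, 0, 0, 0), 6), nrow = 4), name = "safe")
  cfg <- robust_cfg()
  res <- run_trial(safe, cfg, seed = 4)
  expect_equal(res$outcome, "selected")
  expect_equal(res$mtd, 6L)
  expect_equal(sum(res$n_per_dose), 20L)
  # the path climbs exactly one level per cohort until the top
  expect_equal(res$trace$dose[1:6], 1:6)
  expect_true(all(res$trace$dose[7:20] == 6L))
})

test_that("an all-toxic scenario stops early for safety", {
  toxic <- scenario(matrix(rep(c(0, 0, 0, 1), 6), nrow = 4), name = "toxic")
  cfg <- robust_cfg()
  res <- run_trial(toxic, cfg, seed = 4)
  expect_equal(res$outcome, "stopped")
  expect_true(is.na(res$mtd))
  expect_lt(sum(res$n_per_dose), 20L)
  expect_true(all(res$n_per_dose[-1] == 0L))  # never left dose 1
})

test_that("trials are deterministic given the seed and never skip upward", {
  cfg <- robust_cfg()
  for (nm in c("A", "D", "H")) {
    sc <- scenario_preset(nm)
    r1 <- run_trial(sc, cfg, seed = 101)
    r2 <- run_trial(sc, cfg, seed = 101)
    expect_identical(r1$mtd, r2$mtd)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$data$y, r2$data$y)
    d <- r1$trace$dose
    expect_true(all(diff(d) <= 1L))
    expect_true(r1$outcome == "stopped" || sum(r1$n_per_dose) == cfg$max_n)
  }
})

test_that("K=1 ensemble reproduces the single-skeleton quasi-CRM exactly", {
  skels <- default_skeletons()
  full <- robust_cfg()
  for (k in 1:3) {
    single_a <- single_skeleton_design(full, k)
    single_b <- design_config(skels[k],
                              target_profile = c(0.49, 0.18, 0.23, 0.10))
    for (seed in c(3, 17)) {
      ra <- run_trial(scenario_preset("A"), single_a, seed = seed)
      rb <- run_trial(scenario_preset("A"), single_b, seed = seed)
      expect_identical(ra$mtd, rb$mtd)
      expect_equal(ra$trace$dose, rb$trace$dose)
    }
  }
})

test_that("cohorts larger than one share a dose and respect max_n", {
  cfg <- robust_cfg(max_n = 9, cohort_size = 3)
  res <- run_trial(scenario_preset("A"), cfg, seed = 9)
  if (res$outcome == "selected") {
    expect_equal(sum(res$n_per_dose), 9L)
    expect_equal(nrow(res$trace), 3L)
  }
  expect_true(all(res$trace$n == cumsum(rep(3, nrow(res$trace)))))
})

test_that("trial trace records model choice and assignments per cohort", {
  res <- run_trial(scenario_preset("A"), robust_cfg(), seed = 2)
  tr <- trial_trace(res)
  expect_true(all(c("cohort", "dose", "n", "selected_model",
                    "prob_overdose", "stopped", "next_dose") %in% names(tr)))
  expect_equal(tr$cohort, seq_len(nrow(tr)))
  expect_true(all(tr$selected_model %in% 1:3))
  rec <- as_records(res$data)
  expect_equal(nrow(rec), sum(res$n_per_dose))
  expect_equal(rec$y, rec$et / 1.5)
})
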