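# Quasi-Bernoulli engine: power model, quasi-likelihood, saturated QMLE,
# and quadrature posterior vs the dense-grid oracle.

test_that("empiric power model behaves at its anchors and limits", {
  expect_equal(model_prob(0.25, 0), 0.25)
  expect_equal(model_prob(0.25, log(2)), 0.0625)
  expect_equal(model_prob(0.5, -30), 1, tolerance = 1e-9)
  expect_equal(model_prob(0.5, 30), 0, tolerance = 1e-9)
  expect_error(model_prob(1.2, 0), "skeleton_value")
})

test_that("quasi log-likelihood matches direct per-record arithmetic", {
  d1 <- trial_data_from_scores(3, dose = 2, y = 1)
  expect_equal(quasi_log_likelihood(d1, c(0.1, 0.5, 0.9)), log(0.5))
  d2 <- trial_data_from_scores(3, dose = 1, y = 1 / 3)
  expect_equal(quasi_log_likelihood(d2, c(0.2, 0.5, 0.9)),
               (1 / 3) * log(0.2) + (2 / 3) * log(0.8))
  expect_equal(quasi_log_likelihood(trial_data(3), c(0.1, 0.5, 0.9)), 0)
  # reduces to the binomial log-likelihood for binary scores
  d3 <- trial_data_from_scores(2, dose = c(1, 1, 2), y = c(0, 1, 1))
  expect_equal(quasi_log_likelihood(d3, c(0.3, 0.6)),
               dbinom(1, 2, 0.3, log = TRUE) - lchoose(2, 1) + log(0.6))
})

test_that("saturated QMLE is the per-dose mean score and dominates any fit", {
  d <- trial_data_from_scores(4, dose = c(3, 3, 3), y = c(0, 1 / 3, 2 / 3))
  expect_equal(saturated_qmle(d), c(NA, NA, 1 / 3, NA))
  set.seed(8)
  for (i in 1:20) {
    case <- random_case()
    data <- make_data(case)
    sat <- saturated_qmle(data)
    sat_ll <- quasi_log_likelihood(data, ifelse(is.na(sat),
                                                0.5,
                                                pmin(pmax(sat, 1e-12),
                                                     1 - 1e-12)))
    best_fit <- max(vapply(seq(-5, 5, by = 0.01), function(a)
      quasi_log_likelihood(data, case$skeleton ^ exp(a)), 0.0))
    expect_gte(sat_ll + 1e-10, best_fit)
  }
})

test_that("empty data returns the prior: unit marginal and prior-mean curve", {
  mod <- skeleton_model(c(0.11, 0.25, 0.40, 0.55, 0.70, 0.85))
  post <- integrate_posterior(mod, trial_data(6), target_norm = 0.47 / 1.5)
  expect_equal(post$marginal_lik, 1, tolerance = 1e-12)
  oracle <- oracle_posterior(mod$skeleton, integer(0), numeric(0),
                             target_norm = 0.47 / 1.5)
  expect_equal(post$post_probs, oracle$post_probs, tolerance = 1e-8)
  expect_equal(post$prob_overdose_d1, oracle$prob_overdose_d1,
               tolerance = 1e-8)
})

test_that("a toxic observation shifts the whole curve up", {
  mod <- skeleton_model(c(0.11, 0.25, 0.40, 0.55, 0.70, 0.85))
  prior <- integrate_posterior(mod, trial_data(6))
  post <- integrate_posterior(mod,
                              trial_data_from_scores(6, dose = 1, y = 1))
  expect_true(all(post$post_probs > prior$post_probs))
})

test_that("quadrature posterior matches the dense-grid oracle", {
  set.seed(12)
  for (i in 1:10) {
    case <- random_case()
    data <- make_data(case)
    mod <- skeleton_model(case$skeleton)
    post <- integrate_posterior(mod, data, target_norm = 0.3133)
    oracle <- oracle_posterior(case$skeleton, case$dose, case$y,
                               target_norm = 0.3133)
    expect_equal(post$marginal_lik, oracle$marginal_lik,
                 tolerance = 1e-6)
    expect_equal(post$post_probs, oracle$post_probs, tolerance = 1e-6)
    expect_equal(post$prob_overdose_d1, oracle$prob_overdose_d1,
                 tolerance = 1e-6)
  }
})

test_that("posterior toxicity curve is strictly increasing in dose", {
  set.seed(21)
  for (i in 1:15) {
    case <- random_case()
    post <- integrate_posterior(skeleton_model(case$skeleton),
                                make_data(case))
    expect_true(all(diff(post$post_probs) > 0))
  }
})

test_that("adding a toxic (benign) record never lowers (raises) the curve", {
  set.seed(33)
  for (i in 1:10) {
    case <- random_case(max_n = 6)
    data <- make_data(case)
    mod <- skeleton_model(case$skeleton)
    base <- integrate_posterior(mod, data)$post_probs
    j <- sample(seq_along(case$skeleton), 1)
    up <- integrate_posterior(mod, add_score(data, j, 1))$post_probs
    dn <- integrate_posterior(mod, add_score(data, j, 0))$post_probs
    expect_true(all(up >= base - 1e-12))
    expect_true(all(dn <= base + 1e-12))
  }
})

test_that("with binary scores the engine is a standard Bayesian CRM", {
  # dichotomized severity scale: DLT iff grade >= 3, weight s_max
  dlt_scale <- et_scale(weights = c(0, 0, 1.5, 1.5), s_max = 1.5)
  grades <- c(1, 2, 3, 1, 4, 2, 3)
  doses <- c(1, 1, 2, 2, 3, 3, 3)
  data <- add_patients(trial_data(3), doses, grades, dlt_scale)
  expect_true(all(data$y %in% c(0, 1)))
  skel <- c(0.1, 0.3, 0.5)
  post <- integrate_posterior(skeleton_model(skel), data)
  oracle <- oracle_posterior(skel, doses, as.numeric(grades >= 3))
  expect_equal(post$post_probs, oracle$post_probs, tolerance = 1e-6)
})

test_that("invalid skeletons are rejected", {
  expect_error(skeleton_model(c(0.2, 0.2, 0.4)), "skeleton")
  expect_error(skeleton_model(c(0.2, 0.1)), "skeleton")
  expect_error(skeleton_model(c(0, 0.5)), "skeleton")
  expect_error(skeleton_model(c(0.5, 1)), "skeleton")
})
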