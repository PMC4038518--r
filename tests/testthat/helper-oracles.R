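# Independent brute-force oracles. These deliberately avoid the package's
# quadrature path: the quasi-likelihood is recomputed record by record and
# posterior quantities come from a dense trapezoid grid over alpha.

# per-record quasi-Bernoulli likelihood, record by record (no sufficient
# stats), vectorized over a grid of alpha values
oracle_ql <- function(skeleton, dose, y, alpha) {
  out <- rep(1, length(alpha))
  ea <- exp(alpha)
  for (i in seq_along(dose)) {
    p <- skeleton[dose[i]] ^ ea
    out <- out * p^y[i] * (1 - p)^(1 - y[i])
  }
  out
}

# trapezoid integral of f on an equally spaced grid
trapz_grid <- function(x, f) sum((f[-1] + f[-length(f)]) / 2) * (x[2] - x[1])

# posterior summaries on a 20,001-point trapezoid grid over alpha in
# [-10, 10]; the overdose probability integrates the same grid truncated
# at the crossing point c = log(log(theta)/log(p_1)).
oracle_posterior <- function(skeleton, dose, y, target_norm = NULL,
                             prior_mean = 0, prior_sd = sqrt(2)) {
  grid <- seq(-10, 10, length.out = 20001)
  lik <- oracle_ql(skeleton, dose, y, grid)
  dens <- lik * dnorm(grid, prior_mean, prior_sd)
  marg <- trapz_grid(grid, dens)
  post_probs <- vapply(seq_along(skeleton), function(j) {
    trapz_grid(grid, dens * skeleton[j] ^ exp(grid)) / marg
  }, 0.0)
  prob_od <- NA_real_
  if (!is.null(target_norm)) {
    cc <- log(log(target_norm) / log(skeleton[1]))
    gtr <- seq(-10, min(cc, 10), length.out = 20001)
    likt <- oracle_ql(skeleton, dose, y, gtr)
    prob_od <- trapz_grid(gtr, likt * dnorm(gtr, prior_mean, prior_sd)) / marg
  }
  list(marginal_lik = marg, post_probs = post_probs,
       prob_overdose_d1 = prob_od)
}

# random small dataset on a random strictly increasing skeleton
random_case <- function(max_n = 10) {
  J <- sample(3:6, 1)
  repeat {
    skel <- sort(runif(J, 0.01, 0.95))
    if (all(diff(skel) > 0.005)) break
  }
  n <- sample(1:max_n, 1)
  list(skeleton = skel,
       dose = sample(seq_len(J), n, replace = TRUE),
       y = sample(c(0, 1/3, 2/3, 1), n, replace = TRUE))
}

make_data <- function(case) {
  trial_data_from_scores(length(case$skeleton), case$dose, case$y)
}

# extend a dataset by one (dose, normalized score) record
add_score <- function(data, dose, y) {
  trial_data_from_scores(data$J, c(data$dose, dose), c(data$y, y))
}
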