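# Bayesian model selection across skeletons: posterior model probabilities,
# Bayes factors, highest-posterior-model choice, and BMA as a secondary
# estimator.

#' Ensemble of candidate skeleton models
#'
#' Bundles K skeleton models sharing the same dose levels with prior model
#' probabilities P(M_1..M_K). With no a-priori preference the prior weights
#' are uniform, 1/K.
#'
#' @param skeletons list of numeric skeleton vectors (or a single vector),
#'   all of the same length J, each strictly increasing in (0, 1).
#' @param prior_weights prior model probabilities; any non-negative vector,
#'   normalized to sum to 1. Default uniform.
#' @param alpha_prior an [alpha_prior_normal()] shared by all models.
#' @return An object of class `"model_ensemble"` with elements `models`
#'   (list of [skeleton_model()]), `prior_weights`, `K`, `J`.
#' @export
#' @examples
#' ens <- model_ensemble(default_skeletons())
model_ensemble <- function(skeletons, prior_weights = NULL,
                           alpha_prior = alpha_prior_normal()) {
  if (is.numeric(skeletons)) skeletons <- list(skeletons)
  K <- length(skeletons)
  if (K < 1L) stop_field("skeletons", "need at least one skeleton")
  J <- length(skeletons[[1]])
  if (any(vapply(skeletons, length, 0L) != J))
    stop_field("skeletons", "all skeletons must have the same length")
  if (is.null(prior_weights)) prior_weights <- rep(1 / K, K)
  if (length(prior_weights) != K || any(prior_weights < 0) ||
      sum(prior_weights) <= 0)
    stop_field("prior_weights", "need K non-negative weights with positive sum")
  prior_weights <- prior_weights / sum(prior_weights)
  models <- lapply(seq_len(K), function(k)
    skeleton_model(skeletons[[k]], prior_weight = prior_weights[k],
                   alpha_prior = alpha_prior))
  structure(list(models = models, prior_weights = prior_weights,
                 K = K, J = J),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("Model ensemble:", x$K, "skeleton(s) over", x$J, "doses\n")
  for (k in seq_len(x$K))
    cat(sprintf("  M%d (w=%.3f): %s\n", k, x$prior_weights[k],
                paste(x$models[[k]]$skeleton, collapse = ", ")))
  invisible(x)
}

#' Joint posterior over an ensemble of skeleton models
#'
#' Runs [integrate_posterior()] under every model, then combines the
#' marginal likelihoods with the prior model probabilities:
#' `P(M_k | D) = L(D | M_k) P(M_k) / sum_l L(D | M_l) P(M_l)`
#' (computed on the log scale for stability). The selected model is the
#' highest-posterior one, ties broken to the smallest index.
#'
#' @param ensemble a [model_ensemble()].
#' @param data a [trial_data()] object.
#' @param target_norm normalized target score (for overdose probabilities).
#' @param order Gauss--Hermite order passed to [integrate_posterior()].
#' @return An object of class `"ensemble_posterior"`: `per_model` (list of
#'   `quasi_posterior`), `post_model_probs`, `bayes_factors_vs_ref`
#'   (BF_k1), `selected` (model index), `selected_probs` (its posterior
#'   toxicity curve), `bma_probs` (model-averaged curve).
#' @export
ensemble_posterior <- function(ensemble, data, target_norm = NULL,
                               order = 150) {
  per_model <- lapply(ensemble$models, integrate_posterior, data = data,
                      target_norm = target_norm, order = order)
  logm <- vapply(per_model, `[[`, 0.0, "log_marginal")
  lw <- log(ensemble$prior_weights) + logm
  lw <- lw - max(lw)
  post <- exp(lw) / sum(exp(lw))
  sel <- which.max(post)  # first maximum = smallest index on exact ties
  pi_mat <- vapply(per_model, `[[`, numeric(ensemble$J), "post_probs")
  structure(list(per_model = per_model,
                 post_model_probs = post,
                 log_marginals = logm,
                 bayes_factors_vs_ref = exp(logm - logm[1]),
                 selected = sel,
                 selected_probs = per_model[[sel]]$post_probs,
                 bma_probs = as.numeric(pi_mat %*% post)),
            class = "ensemble_posterior")
}

#' @export
print.ensemble_posterior <- function(x, ...) {
  cat("Ensemble posterior over", length(x$per_model), "model(s)\n")
  cat("  P(M_k|D):", round(x$post_model_probs, 4), "\n")
  cat("  selected: M", x$selected, "\n", sep = "")
  cat("  selected post_probs:", round(x$selected_probs, 4), "\n")
  invisible(x)
}

#' Posterior model probabilities
#'
#' @inheritParams ensemble_posterior
#' @return Numeric vector of length K summing to 1.
#' @export
posterior_model_probs <- function(ensemble, data, order = 150) {
  ensemble_posterior(ensemble, data, order = order)$post_model_probs
}

#' Bayes factor between two skeleton models
#'
#' `B_kl = L(D | M_k) / L(D | M_l)`, the ratio of marginal likelihoods,
#' independent of the prior model weights.
#'
#' @inheritParams ensemble_posterior
#' @param k,l model indices.
#' @return Positive scalar; `B_kk = 1`.
#' @export
bayes_factor <- function(ensemble, data, k, l, order = 150) {
  stopifnot(k >= 1, k <= ensemble$K, l >= 1, l <= ensemble$K)
  logm <- vapply(ensemble$models, function(m)
    integrate_posterior(m, data, order = order)$log_marginal, 0.0)
  exp(logm[k] - logm[l])
}

#' Highest-posterior-model choice
#'
#' The model used for inference and dose assignment at each decision
#' point: the one with the largest posterior model probability, ties to
#' the smallest index.
#'
#' @inheritParams ensemble_posterior
#' @return Integer model index.
#' @export
select_model <- function(ensemble, data, order = 150) {
  ensemble_posterior(ensemble, data, order = order)$selected
}

#' Bayesian-model-averaged toxicity estimates
#'
#' The posterior-weighted average of the per-model toxicity curves,
#' `sum_k P(M_k|D) * post_probs_k`. Provided as a secondary estimator; the
#' design's default decision statistic is the selected model's curve.
#'
#' @inheritParams ensemble_posterior
#' @return Numeric vector of length J.
#' @export
bma_estimate <- function(ensemble, data, order = 150) {
  ensemble_posterior(ensemble, data, order = order)$bma_probs
}
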