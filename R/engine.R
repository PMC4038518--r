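# One-parameter quasi-CRM engine: empiric power model, normal prior on the
# power parameter, posterior moments by fixed-order Gaussian quadrature.

#' Normal prior for the CRM power parameter
#'
#' The dose-toxicity curve is the empiric power model
#' `pi_j = p_j ^ exp(alpha)`; `alpha` carries a normal prior. The
#' conventional CRM choice, and the default here, is mean 0 and variance 2.
#'
#' @param mean prior mean.
#' @param var prior variance (> 0).
#' @return An object of class `"alpha_prior"`.
#' @export
alpha_prior_normal <- function(mean = 0, var = 2) {
  if (!is.finite(var) || var <= 0) stop_field("var", "must be positive")
  structure(list(mean = mean, var = var, sd = sqrt(var)),
            class = "alpha_prior")
}

#' One CRM model: a skeleton with its prior weight and power-parameter prior
#'
#' A skeleton is the vector of prior guesses of per-dose toxicity
#' probabilities anchoring one candidate model M_k. It must be strictly
#' increasing and lie strictly inside (0, 1) so the power model is
#' identifiable and order-preserving.
#'
#' @param skeleton strictly increasing probabilities in (0, 1).
#' @param prior_weight prior model probability P(M_k) in \[0, 1\].
#' @param alpha_prior an [alpha_prior_normal()].
#' @return An object of class `"skeleton_model"`.
#' @export
skeleton_model <- function(skeleton, prior_weight = 1,
                           alpha_prior = alpha_prior_normal()) {
  if (!is.numeric(skeleton) || length(skeleton) < 1L ||
      any(skeleton <= 0) || any(skeleton >= 1))
    stop_field("skeleton", "entries must lie strictly in (0, 1)")
  if (any(diff(skeleton) <= 0))
    stop_field("skeleton", "must be strictly increasing in dose")
  if (prior_weight < 0 || prior_weight > 1)
    stop_field("prior_weight", "must lie in [0, 1]")
  structure(list(skeleton = as.numeric(skeleton),
                 prior_weight = prior_weight,
                 alpha_prior = alpha_prior,
                 log_skeleton = log(as.numeric(skeleton))),
            class = "skeleton_model")
}

#' Empiric power-model toxicity probability
#'
#' `model_prob(p, alpha) = p ^ exp(alpha)`: equals the skeleton value at
#' `alpha = 0`, increasing in `p`, and sweeping (0, 1) as `alpha` runs over
#' the real line.
#'
#' @param skeleton_value skeleton probability in (0, 1) (vectorized).
#' @param alpha power parameter (vectorized).
#' @return Toxicity probabilities in (0, 1).
#' @export
model_prob <- function(skeleton_value, alpha) {
  if (any(skeleton_value <= 0 | skeleton_value >= 1))
    stop_field("skeleton_value", "must lie strictly in (0, 1)")
  skeleton_value ^ exp(alpha)
}

# quadrature rule cache -----------------------------------------------------

.quad_cache <- new.env(parent = emptyenv())

gh_rule <- function(order) {
  key <- paste0("gh", order)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussHermite(order)
  .quad_cache[[key]]
}

gl_rule <- function(order) {
  key <- paste0("gl", order)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussLegendre(order, -1, 1)
  .quad_cache[[key]]
}

# quasi log-likelihood at a vector of alpha values; data via (n_j, Y_j).
# Returns length(alpha) vector. All terms stay finite: log pi = e^alpha *
# log p is finite, and pi underflows to 0 (log1p(-pi) -> 0) at large alpha.
ql_at_alpha <- function(model, data, alpha) {
  active <- which(data$n_j > 0L)
  if (!length(active)) return(rep(0, length(alpha)))
  ea <- exp(alpha)
  lpi <- ea %o% model$log_skeleton[active]          # Q x |active|
  l1m <- log1p(-exp(lpi))
  as.numeric(lpi %*% data$Y_j[active] +
             l1m %*% (data$n_j[active] - data$Y_j[active]))
}

#' Posterior inference for one skeleton model by Gaussian quadrature
#'
#' Integrates the quasi-Bernoulli likelihood against the normal prior on
#' the power parameter with fixed-order Gauss--Hermite quadrature, giving
#' the marginal likelihood, the posterior-mean toxicity curve, and the
#' posterior mean of alpha. The overdose probability at the lowest dose,
#' `Pr(pi_1 > target_norm | D)`, is a half-line integral in alpha (the
#' event `p_1^exp(alpha) > theta` is `alpha < c` with
#' `c = log(log(theta)/log(p_1))`), evaluated by fixed-order
#' Gauss--Legendre quadrature on the truncated prior range.
#'
#' @param model a [skeleton_model()].
#' @param data a [trial_data()] object (may be empty).
#' @param target_norm normalized target score in (0, 1); needed for the
#'   overdose probability (otherwise `NA`).
#' @param order Gauss--Hermite order. The default, 150, keeps moments
#'   within about 1e-6 relative of a dense-grid reference on small-trial
#'   datasets; see the methods vignette.
#' @return An object of class `"quasi_posterior"`: `post_probs` (posterior
#'   mean toxicity per dose), `post_mean_alpha`, `marginal_lik`,
#'   `log_marginal`, `prob_overdose_d1`, `plugin_probs`
#'   (`p^exp(E[alpha|D])`, exposed for comparison only).
#' @export
integrate_posterior <- function(model, data, target_norm = NULL,
                                order = 150) {
  prior <- model$alpha_prior
  gh <- gh_rule(order)
  a <- prior$mean + sqrt(2) * prior$sd * gh$x
  w <- gh$w / sqrt(pi)
  ll <- ql_at_alpha(model, data, a)
  m <- max(ll)
  Ls <- exp(ll - m)                       # scaled likelihood at nodes
  z <- sum(w * Ls)
  if (!is.finite(z) || z <= 0)
    stop("non-finite quasi-likelihood integrand; check data and skeleton",
         call. = FALSE)
  log_marginal <- m + log(z)
  omega <- w * Ls / z                     # posterior quadrature weights
  PI <- exp(exp(a) %o% model$log_skeleton)
  post_probs <- as.numeric(omega %*% PI)
  post_mean_alpha <- sum(omega * a)
  plugin_probs <- model$skeleton ^ exp(post_mean_alpha)

  prob_od <- NA_real_
  if (!is.null(target_norm)) {
    stopifnot(target_norm > 0, target_norm < 1)
    # Pr(alpha < c | D) with c the crossing point of pi_1 at the target
    cc <- log(log(target_norm) / model$log_skeleton[1])
    lo <- prior$mean - 12 * prior$sd
    if (cc <= lo) {
      prob_od <- 0
    } else {
      gl <- gl_rule(201)
      ag <- (cc + lo) / 2 + (cc - lo) / 2 * gl$x
      wg <- (cc - lo) / 2 * gl$w
      llg <- ql_at_alpha(model, data, ag) - m
      num <- sum(wg * exp(llg) * stats::dnorm(ag, prior$mean, prior$sd))
      prob_od <- min(max(num / z, 0), 1)
    }
  }

  structure(list(post_probs = post_probs,
                 post_mean_alpha = post_mean_alpha,
                 plugin_probs = plugin_probs,
                 marginal_lik = exp(log_marginal),
                 log_marginal = log_marginal,
                 prob_overdose_d1 = prob_od,
                 order = order),
            class = "quasi_posterior")
}

#' @export
print.quasi_posterior <- function(x, ...) {
  cat("Quasi-posterior: E[alpha|D] =", round(x$post_mean_alpha, 4),
      "| log marginal =", round(x$log_marginal, 4), "\n")
  cat("  post_probs:", round(x$post_probs, 4), "\n")
  if (!is.na(x$prob_overdose_d1))
    cat("  Pr(pi_1 > target | D) =", round(x$prob_overdose_d1, 4), "\n")
  invisible(x)
}
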