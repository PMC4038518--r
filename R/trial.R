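# Sequential trial conduct: dose recommendation, safety stopping, and the
# full simulated-trial loop.

#' Dose recommendation from a posterior toxicity curve
#'
#' The candidate is the dose whose estimated toxicity probability is
#' closest to the normalized target, ties broken to the lower dose. When
#' escalation is restricted, the assigned dose may exceed the current dose
#' by at most one level; de-escalation is unrestricted.
#'
#' @param post_probs per-dose posterior toxicity estimates.
#' @param target_norm normalized target score.
#' @param current_dose dose of the most recent cohort.
#' @param escalation_restricted apply the no-skip rule (default `TRUE`).
#' @param allowed optional integer vector restricting the candidate set
#'   (used for the final MTD call, which only considers tried doses).
#' @return Integer dose index.
#' @export
recommend_dose <- function(post_probs, target_norm, current_dose = NULL,
                           escalation_restricted = TRUE, allowed = NULL) {
  idx <- seq_along(post_probs)
  if (!is.null(allowed)) idx <- intersect(idx, allowed)
  stopifnot(length(idx) >= 1L)
  cand <- idx[argmin_ties_low(abs(post_probs[idx] - target_norm))]
  if (!is.null(current_dose) && escalation_restricted &&
      cand > current_dose + 1L)
    cand <- current_dose + 1L
  as.integer(cand)
}

#' Safety stopping rule
#'
#' The trial terminates when even the lowest dose is too toxic: when the
#' posterior probability that its toxicity exceeds the normalized target,
#' `Pr(pi_1 > target_norm | D)`, is larger than the design's stop cutoff.
#' The probability is evaluated under the selected model or under the
#' posterior model mixture, per `config$stop_under`.
#'
#' @param epost an [ensemble_posterior()] computed with `target_norm`.
#' @param config a [design_config()].
#' @return Logical.
#' @export
check_stop <- function(epost, config) {
  p <- overdose_prob(epost, config)
  is.finite(p) && p > config$stop_cutoff
}

overdose_prob <- function(epost, config) {
  od <- vapply(epost$per_model, `[[`, 0.0, "prob_overdose_d1")
  if (config$stop_under == "mixture")
    sum(epost$post_model_probs * od)
  else
    od[epost$selected]
}

decision_probs <- function(epost, config) {
  if (config$decision == "bma") epost$bma_probs else epost$selected_probs
}

#' Run one sequential dose-finding trial
#'
#' Conducts the full adaptive trial against a scenario truth: cohorts are
#' treated at the current dose, grades are drawn from the scenario's
#' per-dose grade distribution (via inverse-CDF of uniforms from the
#' current RNG stream, so a seed fixes the trial path), scores are
#' normalized, the ensemble posterior is updated, the safety rule is
#' checked, and the next dose is the restricted recommendation. After
#' `max_n` patients the final MTD is the unrestricted recommendation over
#' the doses actually tried.
#'
#' @param scenario a [scenario()] with the same number of doses as the
#'   design.
#' @param config a [design_config()].
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   so the trial is fully reproducible.
#' @return An object of class `"trial_result"`: `outcome` (`"selected"` or
#'   `"stopped"`), `mtd` (dose index or `NA`), `data` (final
#'   [trial_data()]), `n_per_dose`, and `trace` (one row per cohort:
#'   cohort, dose, n, selected model, overdose probability, next dose).
#' @export
run_trial <- function(scenario, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- n_doses(scenario)
  if (J != config$ensemble$J)
    stop_field("scenario", "dose count differs from the design's skeletons")
  scale <- config$scale
  data <- trial_data(J)
  current <- config$start_dose
  outcome <- NA_character_
  trace <- vector("list", ceiling(config$max_n / config$cohort_size))
  step <- 0L
  repeat {
    step <- step + 1L
    m <- min(config$cohort_size, config$max_n - n_patients(data))
    u <- stats::runif(m)
    grades <- sample_grade(scenario$sampling_probs[, current], u = u)
    data <- add_patients(data, current, grades, scale)
    epost <- ensemble_posterior(config$ensemble, data, config$target_norm,
                                config$order)
    probs <- decision_probs(epost, config)
    stopped <- check_stop(epost, config)
    full <- n_patients(data) >= config$max_n
    nxt <- if (stopped) {
      NA_integer_
    } else if (full) {
      recommend_dose(probs, config$target_norm,
                     allowed = which(data$n_j > 0L))
    } else {
      recommend_dose(probs, config$target_norm, current,
                     config$escalation_restricted)
    }
    trace[[step]] <- data.frame(
      cohort = step, dose = current, n = n_patients(data),
      selected_model = epost$selected,
      prob_overdose = overdose_prob(epost, config),
      stopped = stopped, next_dose = nxt)
    if (stopped) { outcome <- "stopped"; mtd <- NA_integer_; break }
    if (full) { outcome <- "selected"; mtd <- nxt; break }
    current <- nxt
  }
  structure(list(outcome = outcome, mtd = mtd, data = data,
                 n_per_dose = data$n_j,
                 trace = do.call(rbind, trace[seq_len(step)]),
                 label = config$label),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial (%s): %s", x$label,
              if (x$outcome == "stopped") "stopped for safety"
              else paste("MTD = dose", x$mtd)), "\n")
  cat("  patients per dose:", x$n_per_dose, "\n")
  invisible(x)
}

#' Trial decision trace as a data.frame
#'
#' One row per cohort with the dose given, cumulative sample size, the
#' selected model, the overdose probability at the lowest dose, and the
#' next assignment; suitable for CSV export.
#'
#' @param result a [run_trial()] result.
#' @return data.frame.
#' @export
trial_trace <- function(result) result$trace
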