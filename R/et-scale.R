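#' Equivalent-toxicity (ET) severity scale
#'
#' An ET scale assigns a numeric severity weight to each toxicity-grade
#' category so that ordinal grades enter the likelihood as fractional
#' events. The conventional scale for the four pooled CTC categories
#' (grades 0--1, 2, 3, 4) gives grade 3 -- the classical DLT threshold --
#' a weight of 1, grade 2 a weight of 0.5 and grade 4 a weight of 1.5.
#' Scores are normalized by `s_max`, the maximum attainable ET score, so a
#' normalized score lies in \[0, 1\] and can be treated as a quasi-Bernoulli
#' response.
#'
#' @param weights non-decreasing numeric vector of severity weights, one per
#'   grade category, with `weights[1] == 0` (no toxicity carries no weight).
#' @param s_max normalization maximum; must be positive and at least
#'   `max(weights)`. Defaults to `max(weights)`.
#' @return An object of class `"et_scale"`.
#' @export
#' @examples
#' sc <- et_scale()                       # (0, 0.5, 1, 1.5), s_max = 1.5
#' mean_et_score(c(0.51, 0.19, 0.14, 0.16), sc)
et_scale <- function(weights = c(0, 0.5, 1.0, 1.5), s_max = max(weights)) {
  if (!is.numeric(weights) || length(weights) < 2L || any(!is.finite(weights)))
    stop_field("weights", "must be a numeric vector of length >= 2")
  if (weights[1] != 0)
    stop_field("weights", "first weight (no/minimal toxicity) must be 0")
  if (any(diff(weights) < 0))
    stop_field("weights", "must be non-decreasing in grade severity")
  if (!is.numeric(s_max) || length(s_max) != 1L || !is.finite(s_max) ||
      s_max <= 0 || s_max < max(weights))
    stop_field("s_max", "must be positive and >= max(weights)")
  structure(list(weights = as.numeric(weights), s_max = as.numeric(s_max)),
            class = "et_scale")
}

#' @export
print.et_scale <- function(x, ...) {
  cat("ET scale: weights =", paste(x$weights, collapse = ", "),
      "| s_max =", x$s_max, "\n")
  invisible(x)
}

check_grade_dist <- function(probs, scale = NULL, what = "probs") {
  if (!is_prob_vector(probs))
    stop_field(what, "must be probabilities in [0,1] summing to 1")
  if (!is.null(scale) && length(probs) != length(scale$weights))
    stop_field(what, sprintf("expected %d grade categories, got %d",
                             length(scale$weights), length(probs)))
  invisible(probs)
}

#' Mean ET score of a grade distribution
#'
#' The expected severity at a dose: the dot product of the per-category
#' grade probabilities with the ET severity weights.
#'
#' @param probs probability vector over grade categories (sums to 1).
#' @param scale an [et_scale()].
#' @return The mean ET score, a non-negative scalar bounded by `max(weights)`.
#' @export
mean_et_score <- function(probs, scale = et_scale()) {
  check_grade_dist(probs, scale)
  sum(probs * scale$weights)
}

#' Target ET score from an elicited toxicity profile at the MTD
#'
#' The target is defined through the mix of toxicity grades one is willing
#' to accept at the maximum tolerated dose: its weighted ET score. The
#' normalized target (target divided by `s_max`) is the quantity compared
#' with model-based toxicity probabilities during the trial.
#'
#' @param profile probability vector over grade categories describing the
#'   acceptable grade mix at the MTD.
#' @inheritParams mean_et_score
#' @return A list with `target_et` (ET-score units) and `target_norm`
#'   (`target_et / s_max`, unitless in \[0, 1\]).
#' @export
#' @examples
#' target_from_profile(c(0.49, 0.18, 0.23, 0.10))  # target 0.47, norm 0.3133
target_from_profile <- function(profile, scale = et_scale()) {
  et <- mean_et_score(profile, scale)
  list(target_et = et, target_norm = et / scale$s_max)
}

#' Dose whose mean ET score is closest to the target
#'
#' Identifies the scenario's true MTD: the dose minimizing the absolute
#' distance between its mean ET score and the target ET score, ties broken
#' to the lower (safer) dose.
#'
#' @param scenario a [scenario()] object.
#' @param target_et target ET score (same units as the scale weights).
#' @inheritParams mean_et_score
#' @return Integer dose index.
#' @export
true_mtd <- function(scenario, target_et, scale = et_scale()) {
  et <- mean_et_profile(scenario, scale)
  argmin_ties_low(abs(et - target_et))
}
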