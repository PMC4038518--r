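#' Sequential trial data
#'
#' Holds the per-patient record of a dose-finding trial -- dose index,
#' observed grade category, ET score and normalized score -- together with
#' the per-dose sufficient statistics that drive the quasi-Bernoulli
#' likelihood: `n_j`, the number of patients treated at dose j, and `Y_j`,
#' the sum of their normalized scores.
#'
#' @param J number of dose levels.
#' @return An empty object of class `"trial_data"`.
#' @export
trial_data <- function(J) {
  structure(list(J = as.integer(J),
                 dose = integer(0), grade = integer(0),
                 et = numeric(0), y = numeric(0),
                 n_j = integer(J), Y_j = numeric(J)),
            class = "trial_data")
}

#' Append observed patients to trial data
#'
#' Grades are converted to ET scores through `scale` and normalized by
#' `scale$s_max`, so every stored `y` lies in \[0, 1\].
#'
#' @param data a [trial_data()] object.
#' @param dose dose index (recycled to the length of `grade`).
#' @param grade observed grade-category indices (1-based).
#' @param scale an [et_scale()].
#' @return The updated `trial_data` object.
#' @export
add_patients <- function(data, dose, grade, scale = et_scale()) {
  grade <- as.integer(grade)
  dose <- rep_len(as.integer(dose), length(grade))
  if (any(dose < 1L | dose > data$J)) stop_field("dose", "out of range")
  if (any(grade < 1L | grade > length(scale$weights)))
    stop_field("grade", "out of range for the ET scale")
  et <- scale$weights[grade]
  y <- et / scale$s_max
  data$dose <- c(data$dose, dose)
  data$grade <- c(data$grade, grade)
  data$et <- c(data$et, et)
  data$y <- c(data$y, y)
  for (i in seq_along(dose)) {
    data$n_j[dose[i]] <- data$n_j[dose[i]] + 1L
    data$Y_j[dose[i]] <- data$Y_j[dose[i]] + y[i]
  }
  data
}

#' Build trial data directly from normalized scores
#'
#' Convenience constructor used in tests and engine code when the grade
#' bookkeeping is irrelevant: records are (dose, normalized score) pairs.
#'
#' @param J number of dose levels.
#' @param dose integer vector of dose indices.
#' @param y normalized scores in \[0, 1\].
#' @return A `trial_data` object (grade/et fields left `NA`).
#' @export
trial_data_from_scores <- function(J, dose, y) {
  if (length(dose) != length(y)) stop_field("y", "length mismatch with dose")
  if (any(y < 0 | y > 1)) stop_field("y", "normalized scores must be in [0,1]")
  data <- trial_data(J)
  dose <- as.integer(dose)
  if (length(dose) && any(dose < 1L | dose > J)) stop_field("dose", "out of range")
  data$dose <- dose
  data$grade <- rep(NA_integer_, length(dose))
  data$et <- rep(NA_real_, length(dose))
  data$y <- as.numeric(y)
  data$n_j <- tabulate(dose, J)
  data$Y_j <- as.numeric(vapply(seq_len(J), function(j) sum(y[dose == j]), 0.0))
  data
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Trial data:", length(x$dose), "patients over", x$J, "doses\n")
  cat("  n_j:", x$n_j, "\n  Y_j:", round(x$Y_j, 3), "\n")
  invisible(x)
}

#' Number of patients enrolled
#' @param data a [trial_data()] object.
#' @return Integer.
#' @export
n_patients <- function(data) length(data$dose)

#' Per-patient records as a data.frame
#' @param data a [trial_data()] object.
#' @return data.frame with columns patient, dose, grade, et, y.
#' @export
as_records <- function(data) {
  data.frame(patient = seq_along(data$dose), dose = data$dose,
             grade = data$grade, et = data$et, y = data$y)
}

#' Quasi-Bernoulli log-likelihood of per-dose toxicity probabilities
#'
#' Each patient with normalized score y treated at a dose with modeled
#' toxicity probability pi contributes `y log(pi) + (1-y) log(1-pi)`: the
#' Bernoulli log-likelihood evaluated at a fractional response. The total
#' depends on the data only through the sufficient statistics (n_j, Y_j).
#'
#' @param data a [trial_data()] object.
#' @param probs per-dose toxicity probabilities, each in (0, 1); values of
#'   exactly 0 or 1 yield `-Inf` when contradicted by the data.
#' @return The quasi log-likelihood (<= 0; 0 for empty data).
#' @export
quasi_log_likelihood <- function(data, probs) {
  if (length(probs) != data$J) stop_field("probs", "length must equal J")
  if (any(probs < 0 | probs > 1)) stop_field("probs", "must lie in [0,1]")
  lp <- ifelse(data$Y_j > 0, data$Y_j * log(probs), 0)
  lq <- ifelse(data$n_j - data$Y_j > 0, (data$n_j - data$Y_j) * log1p(-probs), 0)
  sum(lp + lq)
}

#' Saturated quasi-MLE: observed mean normalized score per dose
#'
#' With one free probability per dose the quasi-likelihood is maximized by
#' the observed average normalized ET score at each dose; doses not yet
#' visited have no estimate (`NA`).
#'
#' @param data a [trial_data()] object.
#' @return Numeric vector of length J; `NA` where `n_j == 0`.
#' @export
saturated_qmle <- function(data) {
  out <- rep(NA_real_, data$J)
  seen <- data$n_j > 0L
  out[seen] <- data$Y_j[seen] / data$n_j[seen]
  out
}
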