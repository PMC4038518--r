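# internal helpers shared across modules

#' Round half to even, robust to floating-point representation
#'
#' Standard IEEE `round()` operates on the stored double, so a value whose
#' exact decimal expansion ends in 5 (e.g. 0.115 arising as a sum of exact
#' hundredths times exact halves) may round the "wrong" way because its
#' binary representation falls a hair below the midpoint. Dose-finding
#' summaries here are dot products of probabilities given to 2 decimals with
#' severity weights given to 1 decimal, so exact values are integer multiples
#' of 1e-3 and midpoint cases are common. This helper snaps to the nearest
#' multiple of 1e-8 before deciding, then applies half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties to the even digit.
#' @export
#' @examples
#' round_half_even(c(0.115, 0.705, 0.985), 2)  # 0.12, 0.70, 0.98
round_half_even <- function(x, digits = 2) {
  scaled <- x * 10^digits
  # kill representation noise before testing for a midpoint
  snapped <- round(scaled * 1e8) / 1e8
  lo <- floor(snapped)
  frac <- snapped - lo
  up <- ifelse(abs(frac - 0.5) < 1e-8, lo %% 2 == 1, frac > 0.5)
  (lo + as.numeric(up)) / 10^digits
}

# argmin with ties broken to the smallest index, tolerant of fp noise
argmin_ties_low <- function(x, tol = 1e-9) {
  which(x <= min(x) + tol)[1L]
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

is_prob_vector <- function(p, tol = 1e-9) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol & p <= 1 + tol) &&
    abs(sum(p) - 1) <= tol
}
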