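# Design configuration: target, scale, ensemble, trial-conduct parameters.

#' Reference skeleton set for six dose levels
#'
#' Three prior opinions on the dose-toxicity curve: a fast-rising skeleton
#' from moderate (0.11) to high (0.85) toxicity; a slowly increasing
#' skeleton topping out at 0.20; and values spread evenly over 0.2--0.95.
#' These are the defaults behind [design_preset()].
#'
#' @return Named list of three numeric skeletons of length 6.
#' @export
default_skeletons <- function() {
  list(skeleton1 = c(0.11, 0.25, 0.40, 0.55, 0.70, 0.85),
       skeleton2 = c(0.01, 0.03, 0.07, 0.12, 0.16, 0.20),
       skeleton3 = c(0.20, 0.35, 0.50, 0.65, 0.80, 0.95))
}

#' Trial design configuration
#'
#' Collects everything needed to run a grade-aware CRM trial: the target
#' (as an ET score or a grade profile at the MTD), the severity scale, the
#' skeleton ensemble, the sample-size and cohort rules, the safety-stop
#' cutoff, and the decision statistic.
#'
#' @param skeletons list of skeleton vectors (see [model_ensemble()]).
#' @param target_et target ET score; exactly one of `target_et` and
#'   `target_profile` must be supplied.
#' @param target_profile grade-probability profile at the MTD from which
#'   the target ET score is computed.
#' @param scale an [et_scale()].
#' @param prior_weights prior model probabilities (default uniform).
#' @param alpha_prior an [alpha_prior_normal()].
#' @param max_n maximum number of patients.
#' @param cohort_size patients per cohort.
#' @param start_dose starting dose index.
#' @param stop_cutoff safety cutoff in (0.5, 1): the trial stops when
#'   `Pr(pi_1 > target_norm | D)` exceeds it.
#' @param escalation_restricted if `TRUE` (default), escalation may not
#'   skip dose levels; de-escalation is unrestricted.
#' @param decision `"selection"` (highest-posterior model, the default) or
#'   `"bma"` (model-averaged curve) as the decision statistic.
#' @param stop_under evaluate the overdose probability under the
#'   `"selected"` model (default) or the posterior `"mixture"`.
#' @param order Gauss--Hermite order for posterior integration.
#' @param label design label used in reports.
#' @return An object of class `"design_config"`; fields include the
#'   resolved `target_et`, `target_norm` and `ensemble`.
#' @export
#' @examples
#' cfg <- design_config(default_skeletons(),
#'                      target_profile = c(0.49, 0.18, 0.23, 0.10))
#' cfg$target_et    # 0.47
design_config <- function(skeletons,
                          target_et = NULL, target_profile = NULL,
                          scale = et_scale(),
                          prior_weights = NULL,
                          alpha_prior = alpha_prior_normal(),
                          max_n = 20L, cohort_size = 1L, start_dose = 1L,
                          stop_cutoff = 0.90,
                          escalation_restricted = TRUE,
                          decision = c("selection", "bma"),
                          stop_under = c("selected", "mixture"),
                          order = 150,
                          label = NULL) {
  decision <- match.arg(decision)
  stop_under <- match.arg(stop_under)
  if (is.null(target_et) == is.null(target_profile))
    stop_field("target_et", "supply exactly one of target_et, target_profile")
  if (!is.null(target_profile))
    target_et <- target_from_profile(target_profile, scale)$target_et
  if (target_et <= 0 || target_et > scale$s_max)
    stop_field("target_et", "must lie in (0, s_max]")
  ensemble <- model_ensemble(skeletons, prior_weights, alpha_prior)
  if (start_dose < 1L || start_dose > ensemble$J)
    stop_field("start_dose", "must be a valid dose index")
  if (cohort_size < 1L) stop_field("cohort_size", "must be >= 1")
  if (max_n < cohort_size) stop_field("max_n", "must be >= cohort_size")
  if (stop_cutoff <= 0.5 || stop_cutoff > 1)
    stop_field("stop_cutoff", "must lie in (0.5, 1]")
  if (is.null(label))
    label <- if (ensemble$K == 1L) "quasi-crm" else "robust-quasi-crm"
  structure(list(target_et = target_et,
                 target_norm = target_et / scale$s_max,
                 scale = scale, ensemble = ensemble,
                 max_n = as.integer(max_n),
                 cohort_size = as.integer(cohort_size),
                 start_dose = as.integer(start_dose),
                 stop_cutoff = stop_cutoff,
                 escalation_restricted = isTRUE(escalation_restricted),
                 decision = decision, stop_under = stop_under,
                 order = order, label = label),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf("Design '%s': target ET %.3f (normalized %.4f), K=%d, J=%d\n",
              x$label, x$target_et, x$target_norm, x$ensemble$K,
              x$ensemble$J))
  cat(sprintf("  max_n=%d cohort=%d start=%d stop_cutoff=%.2f %s/%s\n",
              x$max_n, x$cohort_size, x$start_dose, x$stop_cutoff,
              x$decision, x$stop_under))
  invisible(x)
}

#' Packaged design presets
#'
#' `"table2_default"` is the reference configuration of the
#' operating-characteristics study: three six-dose skeletons with uniform
#' prior weights, target ET score 0.47 derived from the MTD grade profile
#' (49%, 18%, 23%, 10%), maximum 20 patients in cohorts of one starting at
#' the lowest dose, no-skip escalation, safety cutoff 0.90. Loaded from
#' the packaged YAML design file via [load_design()].
#'
#' @param name preset name (`"table2_default"`).
#' @return A [design_config()].
#' @export
design_preset <- function(name = "table2_default") {
  name <- match.arg(name, "table2_default")
  path <- system.file("extdata", paste0(name, ".yaml"), package = "rqcrm")
  if (!nzchar(path)) stop("packaged design file not found", call. = FALSE)
  load_design(path)
}

#' Single-skeleton variant of a design
#'
#' Extracts skeleton `k` from a design's ensemble, giving the plain
#' quasi-CRM design used as a comparator.
#'
#' @param config a [design_config()].
#' @param k skeleton index.
#' @param label new label (default `"quasi-crm-k"`).
#' @return A [design_config()] with `K = 1`.
#' @export
single_skeleton_design <- function(config, k, label = NULL) {
  stopifnot(k >= 1, k <= config$ensemble$K)
  if (is.null(label)) label <- paste0("quasi-crm-", k)
  cfg <- config
  cfg$ensemble <- model_ensemble(list(config$ensemble$models[[k]]$skeleton),
                                 alpha_prior =
                                   config$ensemble$models[[k]]$alpha_prior)
  cfg$label <- label
  cfg
}
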