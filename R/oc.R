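# Monte Carlo operating characteristics: selection percentages, patient
# allocation, overdose exposure, early-stop rate.

# per-replicate seeds derived once from the master seed, so results do not
# depend on evaluation order and identical seeds give common random numbers
# across designs (grade draws are inverse-CDF transforms of shared uniforms)
replicate_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Simulate operating characteristics of a design
#'
#' Runs `n_reps` independent seeded trials of `config` against the
#' scenario truth and aggregates: per-dose selection proportion, early-stop
#' proportion, mean patients per dose, and the mean number of patients
#' treated above the scenario's true MTD (the overdose-exposure summary).
#'
#' @param scenario a [scenario()].
#' @param config a [design_config()].
#' @param n_reps number of replicate trials.
#' @param seed master seed; per-replicate seeds are spawned from it.
#' @return An object of class `"oc"`: `label`, `sel_prop` (length J),
#'   `stop_prop`, `mean_n` (length J), `mean_above_mtd`, `true_mtd`,
#'   `n_reps`, `seed`.
#' @export
simulate_oc <- function(scenario, config, n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  J <- n_doses(scenario)
  seeds <- replicate_seeds(seed, n_reps)
  sel <- integer(J)
  stops <- 0L
  n_tot <- numeric(J)
  for (r in seq_len(n_reps)) {
    res <- run_trial(scenario, config, seed = seeds[r])
    if (res$outcome == "stopped") stops <- stops + 1L
    else sel[res$mtd] <- sel[res$mtd] + 1L
    n_tot <- n_tot + res$n_per_dose
  }
  mtd <- true_mtd(scenario, config$target_et, config$scale)
  mean_n <- n_tot / n_reps
  structure(list(label = config$label,
                 scenario = scenario$name,
                 sel_prop = sel / n_reps,
                 stop_prop = stops / n_reps,
                 mean_n = mean_n,
                 mean_above_mtd = sum(mean_n[seq_len(J) > mtd]),
                 true_mtd = mtd,
                 n_reps = n_reps, seed = seed),
            class = "oc")
}

#' @export
print.oc <- function(x, ...) {
  cat(sprintf("OC [%s, scenario %s, %d reps]\n", x$label, x$scenario,
              x$n_reps))
  cat("  selection:", round(x$sel_prop, 3),
      "| stopped:", round(x$stop_prop, 3), "\n")
  cat("  mean n:", round(x$mean_n, 2),
      "| above MTD (dose", x$true_mtd, "):",
      round(x$mean_above_mtd, 3), "\n")
  invisible(x)
}

#' Compare several designs on one scenario with common random numbers
#'
#' Runs [simulate_oc()] for each design with the same master seed. Because
#' grade outcomes are inverse-CDF transforms of per-patient uniforms, the
#' same seed reuses the same underlying draws across designs, sharpening
#' contrasts between them.
#'
#' @param scenario a [scenario()].
#' @param configs list of [design_config()] objects.
#' @param n_reps replicates per design.
#' @param seed master seed shared by all designs.
#' @return List of `"oc"` objects, one per design.
#' @export
compare_designs <- function(scenario, configs, n_reps = 1000, seed = 1) {
  if (inherits(configs, "design_config")) configs <- list(configs)
  lapply(configs, function(cfg) simulate_oc(scenario, cfg, n_reps, seed))
}

#' The four reference designs for one configuration
#'
#' The ensemble design plus each of its single-skeleton quasi-CRM
#' variants, in the layout of the operating-characteristics study
#' (quasi-CRM 1..K followed by the robust ensemble design).
#'
#' @param config a [design_config()] with K >= 1 skeletons.
#' @return List of [design_config()] objects.
#' @export
comparison_designs <- function(config) {
  singles <- lapply(seq_len(config$ensemble$K), function(k)
    single_skeleton_design(config, k))
  c(singles, list(config))
}

#' Tabulate operating characteristics in the summary-table layout
#'
#' One block per scenario: a row of per-dose mean ET scores (rounded
#' half-to-even to 2 decimals, as in the published layout), then for each
#' design a selection row and a mean-patients row carrying the
#' patients-above-MTD total in the last column.
#'
#' @param ocs list of `"oc"` objects (e.g. from [compare_designs()]).
#' @param scenario the [scenario()] they were computed on.
#' @param scale an [et_scale()] for the ET-score row.
#' @return data.frame with columns `scenario`, `row`, `dose1..doseJ`,
#'   `above_mtd`.
#' @export
format_table2 <- function(ocs, scenario, scale = et_scale()) {
  if (inherits(ocs, "oc")) ocs <- list(ocs)
  J <- n_doses(scenario)
  dose_cols <- paste0("dose", seq_len(J))
  empty <- function(row, vals, above = NA_real_) {
    out <- data.frame(scenario = scenario$name, row = row,
                      t(vals), above_mtd = above, check.names = FALSE)
    names(out)[2 + seq_len(J)] <- dose_cols
    out
  }
  blocks <- list(empty("(ET score)",
                       round_half_even(mean_et_profile(scenario, scale), 2)))
  for (oc in ocs) {
    blocks <- c(blocks,
                list(empty(oc$label, oc$sel_prop),
                     empty(paste0(oc$label, " # patients"), oc$mean_n,
                           oc$mean_above_mtd)))
  }
  do.call(rbind, blocks)
}

#' Write an operating-characteristics table to CSV
#'
#' Full-precision CSV that reads back to identical numbers with
#' [utils::read.csv()].
#'
#' @param table data.frame from [format_table2()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_oc_csv <- function(table, path) {
  utils::write.csv(format(table, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
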