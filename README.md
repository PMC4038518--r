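# rqcrm — grade-aware, skeleton-robust dose finding for phase I trials

Phase I oncology trials hunt for the maximum tolerated dose (MTD) with a
handful of patients. Most designs collapse ordinal toxicity grades (CTC
0–4) into a binary "dose-limiting toxicity", which wastes information and
treats a grade 4 renal toxicity like a grade 3. `rqcrm` is for trial
statisticians who want both of the classical fixes at once:

* **Grades, not binaries.** Each grade category carries an *equivalent
  toxicity (ET) severity weight* (defaults 0, 0.5, 1.0, 1.5 for grades
  0–1, 2, 3, 4). A patient's normalized score `y = s / 1.5 ∈ [0, 1]`
  enters a quasi-Bernoulli likelihood as a fractional event,
  `π^y (1−π)^(1−y)`, so a grade 2 moves the posterior a third as far as a
  grade 4.
* **Robustness to the skeleton.** The one-parameter CRM curve
  `π_j = p_j^exp(α)`, `α ~ N(0, 2)`, is fit under several candidate
  skeletons `p_k` at once. Marginal likelihoods
  `L(D|M_k) = ∫ QL(D|α) π(α) dα` give posterior model probabilities
  `P(M_k|D) ∝ L(D|M_k) P(M_k)`; each dose decision uses the
  highest-posterior model (Bayesian model averaging is available as a
  secondary estimator). A mis-guessed skeleton then costs little, because
  the data vote it out.

The dose given to the next cohort is the one whose posterior-mean
toxicity is closest to the normalized target `θ* = 0.47/1.5 ≈ 0.313`
(derived from an accepted grade mix at the MTD), escalation never skips a
level, and the trial stops early if `Pr(π_1 > θ* | D) > 0.90`. A
Monte-Carlo engine replays the design against scenario truths to produce
operating characteristics: selection percentage per dose, patient
allocation, patients treated above the MTD, early-stop rate.

## A worked example

```r
library(rqcrm)

cfg <- design_preset("table2_default")  # 3 skeletons, target ET 0.47, n = 20
sc  <- scenario_preset("A")             # grade-level simulation truth

run_trial(sc, cfg, seed = 7)
#> Trial (robust-quasi-crm): MTD = dose 4
#>   patients per dose: 4 8 2 6 0 0

simulate_oc(sc, cfg, n_reps = 1000, seed = 1)
#> OC [robust-quasi-crm, scenario A, 1000 reps]
#>   selection: 0 0.044 0.406 0.457 0.085 0.008 | stopped: 0
#>   mean n: ... | above MTD (dose 4 ): 2.292
```

Scenario A's true MTD is dose 4 (mean ET score 0.475, closest to the
0.47 target); the design finds it in ~46% of 1,000 simulated 20-patient
trials and treats on average ~2.3 patients above it. The per-dose mean ET
scores themselves come from `mean_et_profile()`:

```r
round_half_even(mean_et_profile(sc), 2)
#> [1] 0.12 0.19 0.34 0.48 0.76 1.05
```

A shell interface wraps the same functions
(`exec/rqcrm score|trial|simulate|compare`), reading YAML design files
like `inst/extdata/table2_default.yaml` and writing CSV reports.

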