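---
title: "Grade-aware dose finding with skeleton-robust quasi-CRM designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grade-aware dose finding with skeleton-robust quasi-CRM designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqcrm)
```

## The problem

Phase I oncology trials search for the maximum tolerated dose (MTD) of a
new agent. Conventional designs dichotomize toxicity into "dose-limiting
toxicity yes/no", discarding the ordinal grade information (CTC grades
0--4) that clinicians actually record. With 20 or so patients in a whole
trial, throwing away the difference between a grade 2 and a grade 4 event
is costly, and for severe, possibly irreversible toxicities it is unsafe.

`rqcrm` implements a continual reassessment method (CRM) that uses the
grades through *equivalent toxicity (ET) scores*, and protects against the
other classical weakness of the CRM -- sensitivity to the prior guesses of
per-dose toxicity (the *skeleton*) -- by Bayesian model selection across
several skeletons.

## Equivalent toxicity scores

Each pooled grade category (0--1, 2, 3, 4) receives a severity weight.
The default scale gives grade 3, the classical DLT threshold, weight 1;
grade 2 counts half as much and grade 4 half again more:

| category | grades 0--1 | grade 2 | grade 3 | grade 4 |
|---|---|---|---|---|
| weight | 0 | 0.5 | 1.0 | 1.5 |

A patient's normalized score $y = s / s_{\max} \in [0,1]$ divides the
observed weight by $s_{\max} = 1.5$, the most severe modeled outcome.
Normalization by the maximum is what makes the target comparable to a DLT
probability: the default target profile at the MTD (49% grade 0--1, 18%
grade 2, 23% grade 3, 10% grade 4) gives a target ET score of
$0.18 \cdot 0.5 + 0.23 \cdot 1 + 0.10 \cdot 1.5 = 0.47$, i.e. a
normalized target $\theta^* = 0.47/1.5 \approx 0.313$, the analogue of a
33% DLT rate.

The MTD of a scenario is the dose whose mean ET score is closest to the
target, ties to the lower dose -- a symmetric-distance rule, chosen
because the reference operating table marks a dose *above* the target
(0.48 vs 0.47) as the MTD, which a "highest dose not exceeding" rule
would not do.

## The quasi-Bernoulli likelihood

A normalized score is not a Bernoulli outcome, but it can be treated as a
fractional event: patient $i$ at dose $d(i)$ with score $y_i$ contributes

$$\pi_{d(i)}^{\,y_i}\,(1 - \pi_{d(i)})^{\,1 - y_i}$$

to a quasi-Bernoulli likelihood. Because the Bernoulli family is linear
exponential, the quasi-MLE of the mean structure is consistent when the
dose-toxicity model is right, and without any model the saturated
quasi-MLE is simply the observed mean score per dose
(`saturated_qmle()`). When all scores are 0/1 the likelihood *is* the
binomial likelihood, so the machinery degrades gracefully to a standard
CRM on dichotomized data (this equivalence is tested).

## Dose-toxicity model, prior, and model selection

Each candidate model $M_k$ is the empiric power curve
$\pi_j = p_{kj}^{\exp(\alpha)}$ anchored at skeleton
$p_k = (p_{k1} < \dots < p_{kJ})$, with $\alpha \sim N(0, 2)$. The normal
prior with variance 2 is the conventional one-parameter-CRM choice; it is
configurable (`alpha_prior_normal()`), as nothing in the method depends
on it structurally.

Given data $D$, the marginal likelihood
$L(D \mid M_k) = \int QL(D \mid \alpha)\,\pi(\alpha)\,d\alpha$ combines
with prior model weights $P(M_k)$ (uniform by default) into posterior
model probabilities

$$P(M_k \mid D) = \frac{L(D \mid M_k) P(M_k)}{\sum_l L(D \mid M_l) P(M_l)},$$

equivalently expressible through Bayes factors $B_{k1}$ against a
reference model (both routes are computed and must agree to 1e-10 in the
tests). At each decision the design *selects* the highest-posterior model
(ties to the smallest index, for determinism) and recommends the dose
whose posterior-mean toxicity $\hat\pi_j = E[p_{kj}^{\exp(\alpha)} \mid D]$
is closest to $\theta^*$. Model *averaging* (`bma_estimate()`) is exposed
as a secondary estimator behind `decision = "bma"`; selection is the
default because it is the rule the design is built around.

The point estimate is the posterior mean of the curve, not the curve at
the posterior mean of $\alpha$; the plug-in variant is exposed in
`quasi_posterior$plugin_probs` for comparison but never drives decisions.

## Trial conduct

Cohorts (default size 1) start at the lowest dose. After each cohort the
posterior is updated and:

1. **Safety stop.** If $\Pr(\pi_1 > \theta^* \mid D)$ exceeds the cutoff
   (default 0.90), the trial terminates: even the lowest dose is too
   toxic. The probability is evaluated under the selected model by
   default (`stop_under = "mixture"` switches to the posterior-weighted
   mixture); the choice matters little in practice because the rule fires
   only when all models agree the lowest dose is hot.
2. **Assignment.** The next cohort gets the dose with $\hat\pi_j$ closest
   to $\theta^*$ (ties low), restricted so escalation never skips a
   level; de-escalation may skip, which is standard practice since the
   restriction exists to protect patients from untested high doses.
3. **Final call.** After `max_n` patients the MTD is the unrestricted
   recommendation *among doses actually tried* -- the design never
   recommends a dose no patient received.

Everything is deterministic given a seed: grade outcomes are inverse-CDF
transforms of per-patient uniforms, so two designs run with the same seed
see the same latent patients (common random numbers).

## Numerical choices

* **Quadrature.** Posterior moments use fixed-order Gauss--Hermite
  quadrature against the normal prior. The order defaults to 150: on a
  reference suite of 100 random small-trial datasets the worst relative
  disagreement with a 20,001-point trapezoid grid over
  $\alpha \in [-10, 10]$ is about $3 \times 10^{-3}$ at order 50,
  $2 \times 10^{-5}$ at order 100 and $2 \times 10^{-7}$ at order 150, so
  150 is the smallest of these meeting a 1e-6 relative target with
  margin. Marginal likelihoods are accumulated on the log scale.
* **Overdose probability.** $\{\pi_1 > \theta^*\}$ is the half-line
  $\{\alpha < c\}$ with $c = \log(\log\theta^*/\log p_{k1})$; an
  indicator sampled at Hermite nodes converges far too slowly, so this
  one integral uses fixed-order Gauss--Legendre on
  $[\mu_\alpha - 12\sigma_\alpha,\; c]$ -- still deterministic, accurate
  to the same 1e-6 standard (tested against the truncated trapezoid
  oracle).
* **Empty data.** The prior is proper, so all quantities are defined
  before the first patient: unit marginal likelihood, prior-mean curve,
  uniform model probabilities. No special-casing.
* **Rounding for display.** Published-style score rows round half to
  even on the exact decimal value; IEEE `round()` on doubles gets decimal
  midpoints such as 0.115 wrong, so `round_half_even()` snaps to the
  nearest 1e-8 first.
* **Ties.** Every argmin/argmax (closest dose, model choice) breaks ties
  to the smallest index within a 1e-9 tolerance, so trials are exactly
  reproducible across platforms.

## Packaged scenarios and their quirks

The eight packaged scenario presets (`scenario_preset("A")` ...) are the
grade-probability tables of the reference simulation study. Two
documented defects of the source tables are preserved rather than
silently repaired:

* The summary-table labels C--F and the grade-table row groups disagree;
  the per-dose ET scores printed under C, D, E, F are those of row groups
  E, F, C, D. Presets follow the printed ET rows; `preset_group_map()`
  and `table1_group()` expose the mapping and the verbatim rows.
* Three published columns mis-sum (group B dose 6: 1.06; group D dose 6:
  1.14; group C dose 2: 0.99), yet the printed ET rows are exactly the
  raw dot products of these columns. Scenario objects therefore keep the
  verbatim probabilities for score arithmetic and renormalize columns
  only for sampling (`sampling_probs`).

## What the simulator emulates -- and what it does not

`simulate_oc()` replays the adaptive design against a known static truth:
independent patients, instantaneous outcome observation, perfectly
classified grades, and a time-homogeneous dose-toxicity relationship.
Real trials violate all four (late-onset toxicity, accrual pressure,
grading ambiguity, patient heterogeneity), so passing operating
characteristics here demonstrate the *decision logic*, not clinical
performance. The synthetic-scenario generator `random_scenario()` draws
monotone-in-dose grade tables for property testing; it makes no attempt
to mimic the correlation structure of real dose-toxicity data.

The packaged study sizes follow the reference setting: 1,000 replicates
per scenario/design pair, 20 patients per trial, cohorts of one. The
test suite runs the full 8-scenario, 4-design grid at these sizes once
and reuses it across checks.

## A note on reproducing the reference operating table

With the packaged configuration the study reproduces the reference
selection rates closely in scenarios A, B, E--H. Scenario D (dose 1 just
below target) is the exception: the safety rule with cutoff 0.90 stops
about 13% of replicates, while the reference table reports none (its
rows sum to 1.000) and matches this package almost exactly when the stop
rule is disabled. The cutoff used in the reference study is not
recoverable; the package keeps 0.90 -- the conventional value -- as its
default and documents the sensitivity rather than calibrating to the
table.

## Known limitations

* One-parameter empiric model only; no two-parameter logistic CRM.
* No time-to-event weighting (TITE) -- outcomes must be observed before
  the next assignment.
* The model set is fixed for the trial; skeletons cannot be added or
  dropped adaptively.
* Severity weights are taken as given; eliciting them from clinicians is
  outside scope.

## A worked example

```{r example, eval = FALSE}
cfg <- design_preset("table2_default")
sc  <- scenario_preset("A")
run_trial(sc, cfg, seed = 7)
simulate_oc(sc, cfg, n_reps = 1000, seed = 1)
```
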