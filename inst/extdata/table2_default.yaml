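# Reference design: three six-dose skeletons, target ET score from the
# elicited MTD grade profile, 20 patients in cohorts of one, no-skip
# escalation, safety cutoff 0.90.
name: robust-quasi-crm
target_profile: [0.49, 0.18, 0.23, 0.10]
et_weights: [0.0, 0.5, 1.0, 1.5]
s_max: 1.5
skeletons:
  - [0.11, 0.25, 0.40, 0.55, 0.70, 0.85]
  - [0.01, 0.03, 0.07, 0.12, 0.16, 0.20]
  - [0.20, 0.35, 0.50, 0.65, 0.80, 0.95]
prior_weights: uniform
alpha_prior_mean: 0.0
alpha_prior_var: 2.0
max_n: 20
cohort_size: 1
start_dose: 1
stop_cutoff: 0.90
escalation_restricted: true
decision: selection
stop_under: selected
quad_order: 150
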