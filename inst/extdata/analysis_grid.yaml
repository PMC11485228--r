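# Example analysis grid: primary analysis plus the main robustness
# variants and the other outcomes.
defaults:
  landmark: 0.25
  horizon: 6
  caliper: 0.1
analyses:
  - analysis_id: primary
    outcome: dementia
    sex_stratify: true
  - analysis_id: aligned_cohortwise
    outcome: dementia
    followup_alignment: cohortwise
  - analysis_id: restricted_window
    outcome: dementia
    exposure_window_months: 6
  - analysis_id: pre_pandemic
    outcome: dementia
    exposure_window_months: 6
    restrict_followup: 1.5
  - analysis_id: cem_parametric
    outcome: dementia
    matching: cem
  - analysis_id: cem_bootstrap
    outcome: dementia
    matching: cem
    variance: bootstrap
  - analysis_id: zoster
    outcome: zoster
  - analysis_id: mortality
    outcome: mortality
  - analysis_id: negative_control
    outcome: negative_control
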