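# Two-era step-change scenario with covariate drift, waning protective
# era effect on the dementia-like outcome (stronger in females), a
# stronger protective effect on the zoster-like outcome, and null
# mortality / negative-control outcomes.
scenario: paper-like
n_comparator: 20000
n_primary: 20000
seed: 1
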