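# Paper-like era effects without covariate drift between eras.
scenario: no-drift
n_comparator: 20000
n_primary: 20000
seed: 1
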