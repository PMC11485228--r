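# Fully null scenario: no era effects, no drift, identical censoring.
scenario: "null"
n_comparator: 5000
n_primary: 5000
seed: 1
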