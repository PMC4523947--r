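study: study1
n_sides: 3
n_conformations: 2
preset: test_small
rule: hebb
epochs: 20
seed: 1
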