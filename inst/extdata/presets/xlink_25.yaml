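# 25% of 5000 connectors are cross-linkers (1250), 75% motors (3750)
n_filaments: 1000
n_motors: 3750
n_crosslinkers: 1250
n_steps: 1000
seed: 1
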