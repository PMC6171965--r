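# 75% cross-linkers (3750) vs 25% motors (1250): aster formation inhibited
n_filaments: 1000
n_motors: 1250
n_crosslinkers: 3750
n_steps: 1000
seed: 1
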