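# 10% of filaments anchored in the bottom fourth, turnover-exempt
init: anchored
n_filaments: 1000
n_motors: 5000
n_steps: 1000
seed: 1
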