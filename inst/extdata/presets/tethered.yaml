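# motors in the bottom eighth tethered by one head (~12.5% of the total)
init: tethered
n_filaments: 1000
n_motors: 5000
n_steps: 3000
seed: 1
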