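# high filament turnover (p2 = 5/s): no asters form
n_filaments: 1000
n_motors: 5000
filament_turnover_rate: 5
n_steps: 1000
seed: 1
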