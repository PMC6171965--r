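# filaments nucleated on a fixed bar; stabilised against turnover
init: bar
n_filaments: 1000
n_motors: 5000
filament_turnover_rate: 0
n_steps: 1000
seed: 1
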