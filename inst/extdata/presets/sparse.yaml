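# sparse minimal network: 50 filaments, 250 motors, standard parameters
n_filaments: 50
n_motors: 250
n_steps: 1000
seed: 1
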