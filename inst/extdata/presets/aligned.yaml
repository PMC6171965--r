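# initially co-oriented filaments (0..22.5 degrees) with cross-linkers
init: aligned
n_filaments: 1000
n_motors: 3750
n_crosslinkers: 1250
n_steps: 1000
seed: 1
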