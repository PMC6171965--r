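# form an aster for 1000 steps, then drop motor attachment 10 -> 1/s
n_filaments: 1000
n_motors: 5000
n_steps: 2000
seed: 1
switch_schedule:
  - step: 1000
    field: motor_attach_rate
    value: 1
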