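# start with compliant motors (k = 0.5, no central aster), rescue to k = 3
n_filaments: 1000
n_motors: 5000
motor_stiffness: 0.5
n_steps: 2000
seed: 1
switch_schedule:
  - step: 1000
    field: motor_stiffness
    value: 3
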