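scenario: insulin_pump
seed: 42
horizon: 1440
dt: 1
patient:
  profile:
    gender: male
    weight: 84.3
    height: 169.8
    group: 1
  initial:
    gl: 119
pump:
  capacity_ml: 3.15
  basal_profile: standard
corrective_times: [481, 901]
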