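scenario: diabetic_closed_loop
seed: 42
horizon: 600
dt: 0.5
cohort:
  n: 200
patient:
  profile:
    gender: female
    weight: 84.3
    height: 169.8
    group: 1
disturbances:
  - {time: 120, channel: D, magnitude: 1.5, duration: 30}
  - {time: 420, channel: D, magnitude: 1.0, duration: 20}
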