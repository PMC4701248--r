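scenario: icu_monitoring
seed: 42
horizon: 60
dt: 1
cohort:
  n: 200
patient:
  profile:
    gender: female
    weight: 84.3
    height: 169.8
    group: 1
  initial:
    hr: 87
    rr: 19
    sbp: 117
    pt: 37.3
    gl: 119
sensors:
  - {signal: hr, period: 3}
  - {signal: rr, period: 3}
  - {signal: sbp, period: 5}
  - {signal: pt, period: 5}
  - {signal: gl, period: 10}
interventions:
  - {time: 30, sign: gl, value: 160}
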