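# Four-population demonstration scenario: GP targets span the membrane-order
# range, brightness ratios 1/2/4/8 span the size range, plus a buffer control.
seed: 1
samples:
  - sample_id: sample
    condition: demo
    n_events: 20000
    acquisition_minutes: 2
    populations:
      - {name: A, fraction: 0.4, log_brightness_mean: 5.99, gp_target: -0.4}
      - {name: B, fraction: 0.3, log_brightness_mean: 6.68, gp_target: -0.1}
      - {name: C, fraction: 0.2, log_brightness_mean: 7.38, gp_target: 0.2}
      - {name: D, fraction: 0.1, log_brightness_mean: 8.07, gp_target: 0.4}
  - sample_id: buffer
    role: buffer
    n_events: 0
    acquisition_minutes: 2
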