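# Example run configuration (all keys optional; defaults follow the
# simultaneous-integrated-boost prostate protocol).
prescriptions:
  PTV: 60.1
  Boost: 74.0
fractions: 33
beams: [0, 30, 60, 90, 120, 150, 180, 210, 240, 270, 300, 330]
dose_resolution: 2
reference_dose: 76.2
optimizer:
  iterations: 25
  step_mm: 2
  leaf_sweeps: 2
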