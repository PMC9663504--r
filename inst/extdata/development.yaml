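name: development
regions:
  boundaries:
  - '0'
  - '0.14999999999999999'
  - '0.34999999999999998'
  - '0.65000000000000002'
  - '0.84999999999999998'
  - '1'
loads:
  f_axial:
  - '0.10000000000000001'
  - '0.10000000000000001'
  - '0.10000000000000001'
  - '0.10000000000000001'
  - '0.10000000000000001'
  f_radial:
  - '1'
  - '0.60000000000000009'
  - '0.20000000000000001'
  - '0.60000000000000009'
  - '1'
material:
  young_modulus: '1'
  poisson_ratio: '0.40000000000000002'
constraints: default
normalization: '0.20000000000000001'
center_fraction: '0.20000000000000001'
ramp: linear

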