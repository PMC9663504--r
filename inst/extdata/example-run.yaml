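n_axial: 24
n_radial: 5
n_angular: 16
n_bins: 20
f_axial0: 0.1
f_radial0: 1.0
center_fraction: 0.2
seed: 1

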