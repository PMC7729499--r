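# Demo synthetic-scene configuration for the `generate` CLI command.
width_px: 512
height_px: 512
n_cells: 6
polarized_fraction: 0.5
background_level: 20.0
scale_um_per_px: 0.32
seed: 1
param_ranges:
  body_major_px: [50.0, 70.0]
  body_aspect: [1.2, 2.0]
  protrusion_length_px: [70.0, 130.0]
  protrusion_width_px: [6.0, 10.0]
  nucleus_major_px: [20.0, 28.0]
  nucleus_aspect: [1.0, 1.6]
  nucleus_offset_frac: [0.3, 0.7]
shading:
  amplitude: 0.2
  sigma_frac: 0.4
noise:
  gaussian_sd: 4.0
  poisson: false
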