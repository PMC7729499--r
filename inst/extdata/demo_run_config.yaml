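# Demo pipeline configuration: two small fields, fast to run.
n_fields: 1
scale_um_per_px: 0.5
min_area_px: 150
flatfield: true
smoothing_scale_px: 60
disk_diameter_px: 20
ctcf_mode: standard
seed: 1
scene:
  width_px: 420
  height_px: 420
  n_cells: 4
  polarized_fraction: 0.5
  param_ranges:
    body_major_px: [40.0, 55.0]
    body_aspect: [1.2, 1.8]
    protrusion_length_px: [60.0, 110.0]
    protrusion_width_px: [6.0, 9.0]
    nucleus_major_px: [16.0, 22.0]
    nucleus_aspect: [1.0, 1.5]
    nucleus_offset_frac: [0.3, 0.7]
  shading:
    amplitude: 0.15
    sigma_frac: 0.4
  noise:
    gaussian_sd: 3.0
    poisson: false
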