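stages:
- matrix
- afm
- stats
seed: 1
matrix:
  edge_um: 14.5
  voxel_um: 0.29
  fiber_diameter_um: 0.7
  n_fibers: 30
invasion:
  grid_shape:
  - 3
  - 3
  n_cells: 120
  threshold_um: 8.0
afm:
  E_Pa:
    control: 157.7
    latrunculin: 95.0
  n_cells: 6
  repeats: 5
  protocol: nucleus
  noise_sd_pN: 10.0
  rms_threshold_pN: 150.0
out_dir: confinometry_demo
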