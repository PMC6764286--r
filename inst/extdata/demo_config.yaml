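# Demonstration pipeline configuration: a two-group, two-region depletion
# study at reduced field of view. Any field left out falls back to
# gliaquant::default_config().
seed: 1
output_dir: gliaquant_run
stages:
  simulate: true
  stacks: true
  ihc: true
  fish: true
  stats: true
control: control
design:
  groups:
    group: [control, anti-CSF1]
    n_animals: [4, 4]
    control: [true, false]
  regions:
    region: [fimbria, cortex]
    baseline_density: [14000, 11000]
    cv: [0.10, 0.10]
  depletion:
    group: [anti-CSF1]
    region: [fimbria]
    fraction: [0.65]
stack:
  shape_xyz: [256, 256, 64]
  voxel_xy: 0.592
  voxel_z: 1.5
  min_separation: 12
  n_stacks_per_animal: 3
  smoothing_sigma: 1
  background_radius: 0
  min_volume: 150
  split_touching: true
ihc:
  n_positive_cells: 60
  touching_pair_fraction: 0.2
  shape_xy: [512, 512]
fish:
  target_percent_area: 2.08
  shape_xy: [512, 512]
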