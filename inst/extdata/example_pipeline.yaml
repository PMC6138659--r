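# Minimal pipeline configuration: a small cohort at the default
# calibration, coarser pixels to keep the demo fast.
cohort:
  n_cells: 10
  field_size: 64
  pixel_size: 0.4
  cell_area_mean: 80
  cell_area_sd: 5
  onset_mean_t1: 40
  onset_sd_t1: 8
  plateau_mean: 30
  duration: 200
  seed: 1
phases:
  m: 5
log_level: info
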