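# Example oatpquant pipeline configuration.
# Usage:
#   cfg <- run_config_from_yaml(system.file("extdata/example_config.yaml",
#                                           package = "oatpquant"),
#                               outdir = "out", seed = 1)
#   run_pipeline(cfg)
mode: simulate
outdir: oatpquant_out
seed: 1
log_level: info
positivity_q: 0.99
top_n_degs: 40
generator:
  image_shape: [256, 256]
  pixel_size: 0.325
  cohort_sizes: {gbm: 4, control: 3}
  cell_densities: {myeloid: 1200, astrocyte_tumor: 2000, stromal: 600}
  oatp_fold: {myeloid: 18, astrocyte_tumor: 6.1, stromal: 6.1, vessel: 6}
  blur_sigma: 1
  isoform: OATP1A2
segmentation:
  threshold_method: otsu
  min_object_area: 30
  watershed_split: true
expression:
  samples_per_region: 10
  noise_sd: 0.3
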