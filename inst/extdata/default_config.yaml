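master_seed: 20220414
output_dir: results
design:
  n_subjects: 19
  modalities:
  - CECT
  - MIP
  - MR
  observers: 2
  sessions: 2
  tissues:
  - tumor
  - peritumor
phantom:
  grid_shape:
  - 64
  - 64
  - 64
  spacing:
  - 0.97
  - 0.97
  - 3.0
  lesion_radius_mm:
  - 12.0
  - 12.0
  - 12.0
  lesion_mean_intensity: 120.0
  background_mean_intensity: 80.0
  texture_correlation_length_mm: 4.0
  noise_sd: 15.0
profiles:
  CECT:
    sigma_intra_mm: 1.0
    sigma_inter_mm: 2.0
    bias_mm: 0.0
  MIP:
    sigma_intra_mm: 1.5
    sigma_inter_mm: 3.0
    bias_mm: 0.0
  MR:
    sigma_intra_mm: 0.5
    sigma_inter_mm: 1.0
    bias_mm: 0.0
extraction:
  bin_width: 25.0
  ring_radius_mm: 5.0
analysis:
  icc_threshold: 0.75
  qcd_threshold: 10.0
  quantile_type: 7
  robust_semantics: all
  robust_modality: MR
  comparison_arm: MR1
  pca_fraction: 0.9
write_volumes: yes
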