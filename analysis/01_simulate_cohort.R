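#!/usr/bin/env Rscript
# Stage 1 — simulate the phantom cohort and its delineations.
#
# Builds 19 subjects, each a textured CT-like phantom carrying one ellipsoidal
# lesion, and simulates 12 GTV contours per subject (3 modality-guidance arms
# x 2 observers x 2 sessions) plus the matched 0-5 mm peritumoral rings:
# 456 contours in total. Writes all volumes, masks and the cohort manifest
# under results/cohort/.

library(radrepro)

cfg <- pipeline_config(master_seed = 20220414,
                       output_dir = "results/cohort")
dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
write_config(cfg, file.path(cfg$output_dir, "config.yaml"))

cohort <- generate_cohort(design = radrepro:::config_design(cfg),
                          phantom = radrepro:::config_phantom(cfg),
                          profiles = radrepro:::config_profiles(cfg),
                          ring_radius_mm = cfg$extraction$ring_radius_mm)

img_dir <- file.path(cfg$output_dir, "images")
msk_dir <- file.path(cfg$output_dir, "masks")
dir.create(img_dir, showWarnings = FALSE)
dir.create(msk_dir, showWarnings = FALSE)
for (s in seq_len(cohort$design$n_subjects))
  write_image(cohort$images[[s]], file.path(img_dir, sprintf("sub%02d.nii.gz", s)))
recs <- cohort$records
recs$file <- sprintf("masks/sub%02d_%s_%s.nii.gz", recs$subject,
                     recs$arm_label, recs$tissue)
for (i in seq_len(nrow(recs)))
  write_mask(unpack_mask(cohort$masks[[i]]),
             file.path(cfg$output_dir, recs$file[i]))
write.csv(recs, file.path(cfg$output_dir, "cohort_manifest.csv"),
          row.names = FALSE)

vols <- vapply(seq_len(nrow(recs)), function(i)
  mask_volume_mm3(unpack_mask(cohort$masks[[i]])), numeric(1))
message(sprintf(
  "simulated %d subjects, %d contours (%d tumor / %d peritumor)",
  cohort$design$n_subjects, nrow(recs), sum(recs$tissue == "tumor"),
  sum(recs$tissue == "peritumor")))
message(sprintf("tumor GTV volumes: %.1f-%.1f cm3 (mean %.1f cm3)",
                min(vols[recs$tissue == "tumor"]) / 1000,
                max(vols[recs$tissue == "tumor"]) / 1000,
                mean(vols[recs$tissue == "tumor"]) / 1000))
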