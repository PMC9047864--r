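#!/usr/bin/env Rscript
# Stage 2 — extract the 107-feature radiomic vector for every contour.
#
# Re-reads the stage-1 manifest, extracts first-order, shape, GLCM, GLRLM,
# GLSZM, GLDM and NGTDM features (fixed bin width 25, no resampling, no image
# filters) from each image/mask pair, and writes the 456 x 107 feature table.

library(radrepro)

cohort_dir <- "results/cohort"
cfg <- read_config(file.path(cohort_dir, "config.yaml"))
recs <- read.csv(file.path(cohort_dir, "cohort_manifest.csv"))

images <- lapply(seq_len(cfg$design$n_subjects), function(s)
  read_image(file.path(cohort_dir, sprintf("images/sub%02d.nii.gz", s))))

feats <- matrix(NA_real_, nrow(recs), 107,
                dimnames = list(NULL, feature_name_table()$name))
for (i in seq_len(nrow(recs))) {
  msk <- read_mask(file.path(cohort_dir, recs$file[i]))
  feats[i, ] <- extract_all_features(images[[recs$subject[i]]], msk,
                                     bin_width = cfg$extraction$bin_width)
  if (i %% 100 == 0) message("extracted ", i, "/", nrow(recs))
}
ft <- cbind(recs[setdiff(names(recs), "file")], as.data.frame(feats))
dir.create("results", showWarnings = FALSE)
write.csv(ft, "results/features.csv", row.names = FALSE)
message(sprintf("feature table: %d rows x %d feature columns (all finite: %s)",
                nrow(ft), ncol(feats), all(is.finite(feats))))
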