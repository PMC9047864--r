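#!/usr/bin/env Rscript
# Stage 3 — reliability screening.
#
# Per feature: QCD across subjects within each of the 12 arms, and the
# two-way random-effects absolute-agreement ICC for each of the 6 arm pairs
# within every modality and tissue. Counts features with QCD < 10% (small
# variation) and ICC >= 0.75 (excellent reliability), and selects the robust
# set: excellent in all MR pairs and small variation in all MR arms, in both
# tumor and peritumor tissue.

library(radrepro)

cfg <- read_config("results/cohort/config.yaml")
features <- read.csv("results/features.csv", check.names = FALSE)

icc_records <- list(); qcd_records <- list()
for (m in cfg$design$modalities) {
  for (tis in cfg$design$tissues) {
    tabs <- arm_feature_tables(features, m, tis)
    icc_records[[paste(m, tis)]] <- cbind(pairwise_icc(tabs, tissue = tis),
                                          modality = m)
    qcd_records[[paste(m, tis)]] <- cbind(arm_qcd(tabs, tissue = tis),
                                          modality = m)
  }
}
icc_rec <- do.call(rbind, icc_records)
qcd_rec <- do.call(rbind, qcd_records)
write.csv(icc_rec, "results/icc_records.csv", row.names = FALSE)
write.csv(qcd_rec, "results/qcd_records.csv", row.names = FALSE)

counts <- count_meeting(icc_rec, qcd_rec,
                        icc_threshold = cfg$analysis$icc_threshold,
                        qcd_threshold = cfg$analysis$qcd_threshold)
robust <- select_robust(icc_rec[icc_rec$modality == "MR", ],
                        qcd_rec[qcd_rec$modality == "MR", ],
                        semantics = cfg$analysis$robust_semantics)
rep_ <- report_counts(counts, robust = robust)
write.csv(rep_$icc_by_pair, "results/icc_counts.csv", row.names = FALSE)
write.csv(rep_$qcd_by_arm, "results/qcd_counts.csv", row.names = FALSE)
write.csv(rep_$icc_group_means, "results/icc_group_means.csv",
          row.names = FALSE)
write.csv(rep_$robust, "results/robust_features.csv", row.names = FALSE)

gm <- rep_$icc_group_means[rep_$icc_group_means$tissue == "tumor", ]
message("mean excellent-ICC counts (tumor): ",
        paste(sprintf("%s %s = %s", gm$modality, gm$pair_type, gm$rendered),
              collapse = "; "))
message(length(robust), " robust feature(s): ",
        paste(robust, collapse = ", "))
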