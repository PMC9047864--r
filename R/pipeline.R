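# End-to-end pipeline: simulate cohort -> peritumoral rings -> feature
# extraction -> QCD/ICC screening -> robust selection -> tumor/peritumor
# comparison -> PCA. Every artifact is written under config$output_dir and
# hashed into a JSON run manifest; identical config + seed reproduce
# identical hashes.

#' Run the full reproducibility-screening pipeline
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with the run `manifest` and the in-memory
#'   results (`cohort`, `features`, `icc_records`, `qcd_records`, `counts`,
#'   `robust`, `comparison`, `pca`).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            ...)
  t_start <- Sys.time()
  partial <- file.path(out_dir, "RUN.partial")
  writeLines("pipeline started", partial)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c("pipeline failed", paste("stage:", name),
                   conditionMessage(e)), partial)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  say("simulating cohort (", config$design$n_subjects, " subjects)")
  cohort <- stage("simulate", generate_cohort(
    design = config_design(config),
    phantom = config_phantom(config),
    profiles = config_profiles(config),
    ring_radius_mm = config$extraction$ring_radius_mm))

  files <- character(0)
  if (isTRUE(config$write_volumes)) {
    say("writing volumes and masks")
    stage("write-volumes", {
      img_dir <- file.path(out_dir, "images")
      msk_dir <- file.path(out_dir, "masks")
      dir.create(img_dir, showWarnings = FALSE)
      dir.create(msk_dir, showWarnings = FALSE)
      for (s in seq_len(cohort$design$n_subjects)) {
        f <- file.path(img_dir, sprintf("sub%02d.nii.gz", s))
        write_image(cohort$images[[s]], f)
        files <- c(files, f)
      }
      recs <- cohort$records
      mask_files <- character(nrow(recs))
      for (i in seq_len(nrow(recs))) {
        f <- file.path(msk_dir, sprintf("sub%02d_%s_%s.nii.gz",
                                        recs$subject[i], recs$arm_label[i],
                                        recs$tissue[i]))
        write_mask(unpack_mask(cohort$masks[[i]]), f)
        mask_files[i] <- f
      }
      files <- c(files, mask_files)
      manifest_csv <- cbind(recs, file = mask_files)
      f <- file.path(out_dir, "cohort_manifest.csv")
      utils::write.csv(manifest_csv, f, row.names = FALSE)
      files <- c(files, f)
    })
  }

  say("extracting 107 features for ", nrow(cohort$records), " records")
  features <- stage("extract", cohort_feature_table(
    cohort, bin_width = config$extraction$bin_width, verbose = verbose))
  f <- file.path(out_dir, "features.csv")
  utils::write.csv(features, f, row.names = FALSE)
  files <- c(files, f)

  say("reliability screening (QCD / ICC)")
  screen <- stage("reproducibility", {
    icc_records <- list(); qcd_records <- list()
    for (m in config$design$modalities) {
      for (tis in config$design$tissues) {
        tabs <- arm_feature_tables(features, m, tis)
        icc_records[[paste(m, tis)]] <- cbind(
          pairwise_icc(tabs, tissue = tis), modality = m)
        qcd_records[[paste(m, tis)]] <- cbind(
          arm_qcd(tabs, tissue = tis), modality = m)
      }
    }
    list(icc = do.call(rbind, icc_records), qcd = do.call(rbind, qcd_records))
  })
  rownames(screen$icc) <- rownames(screen$qcd) <- NULL
  counts <- count_meeting(screen$icc, screen$qcd,
                          icc_threshold = config$analysis$icc_threshold,
                          qcd_threshold = config$analysis$qcd_threshold)
  for (nm in c("icc_records", "qcd_records")) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(screen[[sub("_records", "", nm)]], f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "icc_counts.csv")
  utils::write.csv(counts$icc_counts, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "qcd_counts.csv")
  utils::write.csv(counts$qcd_counts, f, row.names = FALSE)
  files <- c(files, f)

  say("robust feature selection")
  rm_ <- config$analysis$robust_modality
  robust <- stage("select-robust", select_robust(
    screen$icc[screen$icc$modality == rm_, ],
    screen$qcd[screen$qcd$modality == rm_, ],
    icc_threshold = config$analysis$icc_threshold,
    qcd_threshold = config$analysis$qcd_threshold,
    semantics = config$analysis$robust_semantics))
  f <- file.path(out_dir, "robust_features.csv")
  utils::write.csv(data.frame(feature = robust), f, row.names = FALSE)
  files <- c(files, f)

  say("tumor vs peritumor comparison (", length(robust), " robust features)")
  comparison <- stage("compare", {
    arm <- config$analysis$comparison_arm
    rows <- lapply(robust, function(feat) {
      tum <- features[features$arm_label == arm &
                        features$tissue == "tumor", feat]
      per <- features[features$arm_label == arm &
                        features$tissue == "peritumor", feat]
      cc <- compare_tissues(tum, per)
      data.frame(feature = feat, test = cc$test, statistic = cc$statistic,
                 p_value = cc$p_value, significant = cc$significant,
                 mean_tumor = cc$group_means[["tumor"]],
                 mean_peritumor = cc$group_means[["peritumor"]],
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(feature = character(), test = character(),
                 statistic = numeric(), p_value = numeric(),
                 significant = logical(), mean_tumor = numeric(),
                 mean_peritumor = numeric())
  })
  f <- file.path(out_dir, "comparison.csv")
  utils::write.csv(comparison, f, row.names = FALSE)
  files <- c(files, f)

  say("PCA dimensionality reduction")
  pca <- stage("pca", {
    arm <- config$analysis$comparison_arm
    out <- list()
    for (tis in config$design$tissues) {
      # features with excellent reliability in every pair of the robust
      # modality for this tissue feed the PCA
      ic <- screen$icc[screen$icc$modality == rm_ &
                         screen$icc$tissue == tis, ]
      ok <- tapply(!is.na(ic$icc) &
                     ic$icc >= config$analysis$icc_threshold,
                   ic$feature, all)
      sel <- names(ok)[ok]
      if (length(sel) < 1L) { out[[tis]] <- NULL; next }
      X <- features[features$arm_label == arm & features$tissue == tis,
                    sel, drop = FALSE]
      pr <- pca_reduce(X)
      pr$n_retain <- n_components_for(pr, config$analysis$pca_fraction)
      pr$n_features_in <- length(sel)
      out[[tis]] <- pr
    }
    out
  })
  for (tis in names(pca)) {
    pr <- pca[[tis]]
    f <- file.path(out_dir, paste0("pca_summary_", tis, ".csv"))
    utils::write.csv(data.frame(
      component = seq_along(pr$eigenvalues), eigenvalue = pr$eigenvalues,
      proportion = pr$proportion, cumulative = pr$cumulative),
      f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, paste0("pca_scores_", tis, ".csv"))
    utils::write.csv(as.data.frame(pr$scores), f, row.names = FALSE)
    files <- c(files, f)
  }

  say("writing run manifest")
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_file)
  files <- c(files, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radrepro")),
    master_seed = config$master_seed,
    n_records = nrow(cohort$records),
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    files = lapply(stats::setNames(files, files),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(partial)
  invisible(list(manifest = manifest, cohort = cohort, features = features,
                 icc_records = screen$icc, qcd_records = screen$qcd,
                 counts = counts, robust = robust, comparison = comparison,
                 pca = pca))
}
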