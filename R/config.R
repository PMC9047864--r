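# Pipeline configuration: a nested list that round-trips losslessly through
# YAML. Unknown keys are rejected so typos fail loudly instead of silently
# falling back to defaults.

#' Default pipeline configuration
#'
#' @param master_seed Master RNG seed.
#' @param output_dir Output directory for [run_pipeline()].
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 20220414, output_dir = "results") {
  structure(list(
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    design = list(
      n_subjects = 19L,
      modalities = c("CECT", "MIP", "MR"),
      observers = 2L,
      sessions = 2L,
      tissues = c("tumor", "peritumor")),
    phantom = list(
      grid_shape = c(64L, 64L, 64L),
      spacing = c(0.97, 0.97, 3.0),
      lesion_radius_mm = c(12, 12, 12),
      lesion_mean_intensity = 120,
      background_mean_intensity = 80,
      texture_correlation_length_mm = 4,
      noise_sd = 15),
    profiles = list(
      CECT = list(sigma_intra_mm = 1.0, sigma_inter_mm = 2.0, bias_mm = 0),
      MIP  = list(sigma_intra_mm = 1.5, sigma_inter_mm = 3.0, bias_mm = 0),
      MR   = list(sigma_intra_mm = 0.5, sigma_inter_mm = 1.0, bias_mm = 0)),
    extraction = list(
      bin_width = 25,
      ring_radius_mm = 5),
    analysis = list(
      icc_threshold = 0.75,
      qcd_threshold = 10,
      quantile_type = 7L,
      robust_semantics = "all",
      robust_modality = "MR",
      comparison_arm = "MR1",
      pca_fraction = 0.90),
    write_volumes = TRUE),
    class = "pipeline_config")
}

check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]]))
        stop("configuration key ", path, k, " must be a block")
      check_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(ref, cfg) {
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      ref[[k]] <- merge_config(ref[[k]], cfg[[k]])
    } else {
      ref[[k]] <- cfg[[k]]
    }
  }
  ref
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Values missing from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML path.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(pipeline_config())
  check_keys(raw, ref)
  out <- merge_config(ref, raw)
  out$master_seed <- as.integer(out$master_seed)
  structure(out, class = "pipeline_config")
}

# Materialize typed objects from the configuration blocks.
config_design <- function(config) {
  d <- config$design
  study_design(n_subjects = d$n_subjects, modalities = d$modalities,
               observers = d$observers, sessions = d$sessions,
               tissues = d$tissues, master_seed = config$master_seed)
}

config_phantom <- function(config) {
  do.call(phantom_params, config$phantom)
}

config_profiles <- function(config) {
  out <- lapply(names(config$profiles), function(m) {
    p <- config$profiles[[m]]
    observer_profile(m, p$sigma_intra_mm, p$sigma_inter_mm, p$bias_mm)
  })
  names(out) <- names(config$profiles)
  out
}
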