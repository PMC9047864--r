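# Synthetic study cohort: per subject one phantom, then for every modality x
# observer x session one GTV delineation and its matched peritumoral ring.
# The default design mirrors the study layout: 19 subjects x 3 modality
# guidance arms x 2 observers x 2 sessions x 2 tissues = 456 contours
# (228 tumor + 228 peritumor).

#' Study design for the synthetic cohort
#'
#' @param n_subjects Number of subjects (default 19).
#' @param modalities Character vector of modality-guidance arms.
#' @param observers,sessions Counts of observers and repeat sessions.
#' @param tissues Tissue labels; `"tumor"` is the GTV, `"peritumor"` its
#'   0-5 mm ring.
#' @param master_seed Master RNG seed for the whole cohort.
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 19, modalities = c("CECT", "MIP", "MR"),
                         observers = 2, sessions = 2,
                         tissues = c("tumor", "peritumor"),
                         master_seed = 20220414) {
  if (n_subjects < 1 || observers < 1 || sessions < 1 ||
      length(modalities) < 1 || length(tissues) < 1)
    stop("all design counts must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 modalities = modalities,
                 observers = as.integer(observers),
                 sessions = as.integer(sessions),
                 tissues = tissues,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Expected number of delineation records under a design
#' @param design A [study_design()].
#' @return Integer: subjects x modalities x observers x sessions x tissues.
#' @export
design_record_count <- function(design) {
  design$n_subjects * length(design$modalities) * design$observers *
    design$sessions * length(design$tissues)
}

# Arm index convention: 1,2 = observer 1 sessions 1,2; 3,4 = observer 2
# sessions 1,2 (so within-modality pairs (1,2) and (3,4) are intra-observer).
arm_index <- function(observer, session, n_sessions) {
  (observer - 1L) * n_sessions + session
}

# Per-subject phantom with jittered lesion size/intensity so subjects differ
# (the between-subject variance the ICC partitions).
subject_phantom_params <- function(base, subject, master_seed) {
  with_seed(child_seed(master_seed, "subject", subject, "phantom-params"), {
    scale <- stats::runif(3, 0.75, 1.25)
    p <- base
    p$lesion_radius_mm <- base$lesion_radius_mm * scale
    p$lesion_mean_intensity <- base$lesion_mean_intensity + stats::rnorm(1, 0, 6)
    p
  })
}

#' Generate the full synthetic delineation cohort
#'
#' For each subject a phantom image and true lesion mask are generated (with
#' per-subject jitter of lesion size and mean intensity), then every
#' modality/observer/session combination contributes one simulated GTV plus
#' its peritumoral ring. Fully deterministic given `design$master_seed`.
#'
#' @param design A [study_design()].
#' @param phantom A [phantom_params()] base parameter set.
#' @param profiles Named list of [observer_profile()], one per modality in
#'   the design (default [default_observer_profiles()]).
#' @param ring_radius_mm Outer radius of the peritumoral ring (mm).
#' @return A `cohort_bundle`: `design`, `records` (data.frame with one row
#'   per delineation: subject, tissue, modality, observer, session,
#'   arm_label), `masks` (list of packed masks parallel to `records`),
#'   `images` and `truth` (per-subject lists), `provenance`.
#' @export
generate_cohort <- function(design = study_design(),
                            phantom = phantom_params(),
                            profiles = default_observer_profiles(),
                            ring_radius_mm = 5) {
  missing_prof <- setdiff(design$modalities, names(profiles))
  if (length(missing_prof))
    stop("no observer profile for modality: ",
         paste(missing_prof, collapse = ", "))
  images <- vector("list", design$n_subjects)
  truth <- vector("list", design$n_subjects)
  rows <- list()
  masks <- list()
  rec <- 0L
  for (s in seq_len(design$n_subjects)) {
    ps <- subject_phantom_params(phantom, s, design$master_seed)
    ph <- generate_phantom(ps, child_seed(design$master_seed, "subject", s,
                                          "phantom-image"))
    images[[s]] <- ph$image
    truth[[s]] <- pack_mask(ph$mask)
    for (m in design$modalities) {
      dseed <- child_seed(design$master_seed, "subject", s, "modality", m)
      for (o in seq_len(design$observers)) {
        for (se in seq_len(design$sessions)) {
          gtv <- tryCatch(
            simulate_delineation(ph$mask, profile = profiles[[m]],
                                 observer = o, session = se, seed = dseed),
            error = function(e) stop(sprintf(
              "delineation failed for subject %d, arm %s%d: %s",
              s, m, arm_index(o, se, design$sessions), conditionMessage(e)),
              call. = FALSE))
          ring <- peritumoral_ring(gtv, radius_mm = ring_radius_mm)
          ai <- arm_index(o, se, design$sessions)
          for (tis in design$tissues) {
            msk <- switch(tis, tumor = gtv, peritumor = ring,
                          stop("unknown tissue label: ", tis))
            if (sum(msk$data) == 0L)
              stop(sprintf("empty %s mask for subject %d, arm %s%d",
                           tis, s, m, ai))
            rec <- rec + 1L
            rows[[rec]] <- data.frame(
              record = rec, subject = s, tissue = tis, modality = m,
              observer = o, session = se,
              arm_label = paste0(m, ai), stringsAsFactors = FALSE)
            masks[[rec]] <- pack_mask(msk)
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  stopifnot(nrow(records) == design_record_count(design))
  structure(list(design = design, records = records, masks = masks,
                 images = images, truth = truth,
                 provenance = list(master_seed = design$master_seed,
                                   phantom = phantom,
                                   profiles = profiles,
                                   ring_radius_mm = ring_radius_mm)),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", x$design$n_subjects, " subjects, ",
      nrow(x$records), " delineation records (",
      sum(x$records$tissue == "tumor"), " tumor / ",
      sum(x$records$tissue == "peritumor"), " peritumor)\n", sep = "")
  invisible(x)
}
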