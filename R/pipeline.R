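# End-to-end driver: preprocess every (patient, modality) under each
# resampling arm and extraction dialect, and emit the tidy cohort feature
# table consumed by the agreement module.

ARM_NAMES <- c("original", "internal", "external")

arm_specs <- function(arm, dialect, target_ct, target_mri) {
  # "internal" resampling adopts the dialect's grid anchoring; "external" is
  # a shared prior stage and always corner-anchors, so both dialects see
  # identical externally-resampled inputs (as when one program resamples for
  # both).
  anchor <- if (arm == "internal") dialect$grid_anchor else "corner"
  strategy <- arm
  list(ct = resampling_spec(strategy, target_ct, grid_anchor = anchor),
       mri = resampling_spec(strategy, target_mri, grid_anchor = anchor))
}

fv_rows <- function(fv, pid, modality, dialect_name, arm) {
  data.frame(patient_id = pid, modality = modality, dialect = dialect_name,
             resampling = arm, feature = names(fv$values),
             category = unname(fv$categories),
             value = unname(fv$values),
             degenerate = names(fv$values) %in% fv$degenerate,
             stringsAsFactors = FALSE)
}

#' Extract the cohort feature table
#'
#' Runs preprocess (resample, MRI histogram matching, 64-bin discretization)
#' and feature extraction for every patient x modality x resampling arm x
#' dialect cell of the experimental grid. For "original" and "external" arms
#' preprocessing is dialect-independent and computed once per patient.
#'
#' @param records List of [patient_record()]s.
#' @param arms Subset of c("original", "internal", "external").
#' @param dialects List of [extraction_dialect()]s.
#' @param norm A [normalization_spec()] for MRI (or NULL to skip).
#' @param n_bins Discretization bins (default 64).
#' @param target_ct,target_mri Working spacings for the resampling arms
#'   (defaults 1 mm CT, 1.4 mm MRI).
#' @return Tidy data.frame: `patient_id`, `modality`, `dialect`,
#'   `resampling`, `feature`, `category`, `value`, `degenerate`.
#' @export
extract_cohort <- function(records, arms = ARM_NAMES,
                           dialects = list(extraction_dialect("A"),
                                           extraction_dialect("B")),
                           norm = NULL, n_bins = 64L,
                           target_ct = c(1, 1, 1),
                           target_mri = c(1.4, 1.4, 1.4)) {
  stopifnot(all(arms %in% ARM_NAMES), length(arms) >= 1, length(dialects) >= 1)
  dnames <- vapply(dialects, `[[`, "", "name")
  out <- vector("list", length(records) * length(arms) * length(dialects) * 2)
  idx <- 0L
  for (rec in records) {
    for (arm in arms) {
      shared <- NULL
      if (arm != "internal") {
        specs <- arm_specs(arm, dialects[[1]], target_ct, target_mri)
        shared <- preprocess_pair(rec, specs, norm, n_bins)
      }
      for (di in seq_along(dialects)) {
        dia <- dialects[[di]]
        prep <- if (arm == "internal") {
          preprocess_pair(rec, arm_specs(arm, dia, target_ct, target_mri),
                          norm, n_bins)
        } else shared
        fvs <- extract_record(prep, dia)
        idx <- idx + 1L
        out[[idx]] <- fv_rows(fvs$ct, rec$patient_id, "CT", dnames[di], arm)
        idx <- idx + 1L
        out[[idx]] <- fv_rows(fvs$mri, rec$patient_id, "MRI", dnames[di], arm)
      }
    }
  }
  do.call(rbind, out[seq_len(idx)])
}

#' Run all configured agreement comparisons on a feature table
#'
#' Dialect comparison per (modality x arm) and modality comparison per
#' (dialect x arm), mirroring the study's two analysis tables.
#'
#' @param table Feature table from [extract_cohort()].
#' @param comparisons Subset of c("dialects", "modalities").
#' @return List of `agreement_summary` objects.
#' @export
run_comparisons <- function(table, comparisons = c("dialects", "modalities")) {
  arms <- unique(table$resampling)
  dialects <- unique(table$dialect)
  summaries <- list()
  if ("dialects" %in% comparisons) {
    if (length(dialects) < 2) {
      warning("dialect comparison requested but only ", length(dialects),
              " dialect present; skipping")
    } else {
      for (mod in unique(table$modality))
        for (arm in arms)
          summaries[[length(summaries) + 1L]] <-
            compare_dialects(table, mod, arm, dialects[1:2])
    }
  }
  if ("modalities" %in% comparisons) {
    for (dia in dialects)
      for (arm in arms)
        summaries[[length(summaries) + 1L]] <-
          compare_modalities(table, dia, arm)
  }
  summaries
}
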