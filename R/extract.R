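# Assembly of the per-sequence 107-feature panel and the per-patient
# 428-column row.

feature_family_sizes <- function() {
  c(shape = 14L, firstorder = 18L, glcm = 24L, glrlm = 16L, glszm = 16L,
    gldm = 14L, ngtdm = 5L)
}

#' Canonical names of the 107-feature panel
#'
#' Family-prefixed names (`shape_`, `firstorder_`, `glcm_`, `glrlm_`,
#' `glszm_`, `gldm_`, `ngtdm_`) in the package's canonical order.
#'
#' @return Character vector of length 107.
#' @export
feature_names_107 <- function() {
  c(paste0("shape_", shape_feature_names()),
    paste0("firstorder_", firstorder_feature_names()),
    paste0("glcm_", glcm_feature_names()),
    paste0("glrlm_", glrlm_feature_names()),
    paste0("glszm_", glszm_feature_names()),
    paste0("gldm_", gldm_feature_names()),
    paste0("ngtdm_", ngtdm_feature_names()))
}

#' Extract the 107-feature panel from one sequence
#'
#' Resamples to isotropic spacing, discretizes with a fixed bin width, and
#' computes the shape (14), first-order (18), GLCM (24), GLRLM (16),
#' GLSZM (16), GLDM (14) and NGTDM (5) features.
#'
#' @param volume An [image_volume()].
#' @param mask The matching [roi_mask()].
#' @param bin_width Gray-level bin width in intensity units (default 64).
#' @param target_spacing Isotropic resampling target in mm (default 1).
#' @param resample Set `FALSE` to skip resampling (grids already isotropic).
#' @return Named numeric vector of length 107.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4,
#'   volume_shape = c(16, 16, 16), seed = 1))
#' fv <- extract_features(cohort$volumes[[1]]$T1W, cohort$masks[[1]]$r1s1)
#' length(fv)
extract_features <- function(volume, mask, bin_width = 64, target_spacing = 1,
                             resample = TRUE) {
  if (resample) {
    rs <- resample_isotropic(volume, mask, target_spacing)
    volume <- rs$volume
    mask <- rs$mask
  }
  droi <- discretize(volume, mask, bin_width)
  c(shape = shape_features(mask),
    firstorder = firstorder_features(droi),
    glcm = glcm_features(droi),
    glrlm = glrlm_features(droi),
    glszm = glszm_features(droi),
    gldm = gldm_features(droi),
    ngtdm = ngtdm_features(droi)) |>
    setNames(feature_names_107())
}

#' Extract the 428-column feature row for one patient
#'
#' Runs [extract_features()] on each of the four sequences and registers
#' the per-sequence vectors in one row, sequence-major
#' (T1W, T2W, T1C, FLAIR), with column names `<sequence>_<family>_<name>`.
#'
#' @param volumes Named list of 4 [image_volume()]s (names from
#'   [mri_sequences()]).
#' @param mask An [roi_mask()] shared by the sequences (co-registered), or a
#'   named list of per-sequence masks.
#' @inheritParams extract_features
#' @return Named numeric vector of length `107 * 4 = 428`.
#' @export
extract_patient <- function(volumes, mask, bin_width = 64, target_spacing = 1,
                            resample = TRUE) {
  seqs <- mri_sequences()
  missing <- setdiff(seqs, names(volumes))
  if (length(missing)) {
    abort(sprintf("missing sequence(s): %s", paste(missing, collapse = ", ")))
  }
  per_seq <- lapply(seqs, function(s) {
    m <- if (inherits(mask, "roi_mask")) mask else mask[[s]]
    extract_features(volumes[[s]], m, bin_width, target_spacing, resample)
  })
  out <- unlist(per_seq)
  names(out) <- as.vector(vapply(seqs, function(s) {
    paste(s, feature_names_107(), sep = "_")
  }, character(107)))
  out
}

#' Extract a feature table from a synthetic (or loaded) cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or of the same
#'   shape), with one mask chosen per patient via `occasion`.
#' @param occasion Which repeated segmentation to use (default `"r1s1"`,
#'   reader 1's first session); `"true"` uses the unperturbed mask.
#' @inheritParams extract_features
#' @return A feature table tibble: `patient_id`, `label`, 428 feature
#'   columns.
#' @export
extract_cohort <- function(cohort, occasion = "r1s1", bin_width = 64,
                           target_spacing = 1, resample = TRUE) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    m <- if (identical(occasion, "true")) {
      cohort$mask_true[[i]]
    } else {
      cohort$masks[[i]][[occasion]]
    }
    extract_patient(cohort$volumes[[i]], m, bin_width, target_spacing,
                    resample)
  })
  X <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(patient_id = cohort$patient_id, label = cohort$label),
    tibble::as_tibble(X)
  )
}
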