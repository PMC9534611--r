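# Synthetic two-class cohorts: ellipsoidal lesions with class-dependent
# texture across 4 co-registered sequences, plus repeated segmentations
# (2 readers x 2 sessions) with boundary perturbations for ICC work.

#' Configuration for a synthetic imaging cohort
#'
#' Defaults emulate the study conditions this pipeline targets: 91 patients
#' with a 51:40 glioblastoma:metastasis split, four co-registered MRI
#' sequences at 1 mm isotropic spacing, ellipsoidal tumors whose radius
#' distribution and intensity texture (mean level and spatial correlation
#' length of a Gaussian random field) differ by class, and two readers
#' segmenting twice each with small independent boundary-voxel flips.
#'
#' @param n_patients Number of patients (>= 4).
#' @param class_balance Fraction of class `GBM`, strictly in (0, 1).
#' @param volume_shape Integer length-3 voxel grid per sequence (each >= 8).
#' @param voxel_spacing mm per voxel along each axis.
#' @param tumor_radius_range mm; named list with `GBM` and `MET` elements,
#'   each a length-2 interval for per-axis ellipsoid radii.
#' @param texture Named list with `GBM` and `MET` elements; each has
#'   per-sequence intensity `mean`s (length 4), a noise `sd`, and a spatial
#'   correlation length `corr_len` (mm) of the within-ROI texture field.
#' @param reader_jitter Probability that a boundary-shell voxel flips in a
#'   repeated segmentation (0 disables all perturbation).
#' @param n_readers,n_sessions Repeated-segmentation design (defaults 2 x 2).
#' @param seed Integer; the same seed reproduces the cohort bit for bit.
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 6, volume_shape = c(16, 16, 16), seed = 1)
cohort_config <- function(n_patients = 91,
                          class_balance = 51 / 91,
                          volume_shape = c(28, 28, 28),
                          voxel_spacing = c(1, 1, 1),
                          tumor_radius_range = list(GBM = c(6, 10),
                                                    MET = c(4.5, 8)),
                          texture = list(
                            GBM = list(mean = c(95, 120, 140, 110), sd = 22,
                                       corr_len = 2.2),
                            MET = list(mean = c(105, 105, 120, 100), sd = 16,
                                       corr_len = 1.2)),
                          reader_jitter = 0.05,
                          n_readers = 2,
                          n_sessions = 2,
                          seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 4) {
    abort("`n_patients` must be at least 4.")
  }
  if (!is.numeric(class_balance) || class_balance <= 0 || class_balance >= 1) {
    abort("`class_balance` must lie strictly between 0 and 1.")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 8)) {
    abort("`volume_shape` must have 3 axes of at least 8 voxels.")
  }
  fov <- volume_shape * voxel_spacing
  rmax <- max(unlist(tumor_radius_range))
  if (any(unlist(tumor_radius_range) <= 0) || rmax >= min(fov) / 2) {
    abort("tumor radii must be positive and smaller than half the field of view.")
  }
  if (reader_jitter < 0 || reader_jitter > 1) {
    abort("`reader_jitter` must be a probability.")
  }
  structure(
    list(n_patients = as.integer(n_patients), class_balance = class_balance,
         volume_shape = as.integer(volume_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         tumor_radius_range = tumor_radius_range, texture = texture,
         reader_jitter = reader_jitter, n_readers = as.integer(n_readers),
         n_sessions = as.integer(n_sessions), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Gaussian random field with correlation length `corr_len` mm, zero mean,
# unit variance (empirically normalized), on the given grid.
gaussian_random_field <- function(shape, spacing, corr_len) {
  noise <- array(rnorm(prod(shape)), shape)
  if (corr_len > 0) {
    sig <- corr_len / spacing
    noise <- gaussian_smooth_3d(noise, sig)
  }
  s <- sd(as.vector(noise))
  if (s > 0) noise <- noise / s
  noise
}

mask_shells <- function(mask) {
  nb6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  any_nb_bg <- array(FALSE, dim(mask))
  any_nb_fg <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(nb6))) {
    sh <- shift_array(mask, nb6[i, 1], 1, fill = FALSE)
    sh <- shift_array(sh, nb6[i, 2], 2, fill = FALSE)
    sh <- shift_array(sh, nb6[i, 3], 3, fill = FALSE)
    sh <- array(as.logical(sh), dim(mask))
    any_nb_fg <- any_nb_fg | sh
    any_nb_bg <- any_nb_bg | !sh
  }
  list(inner = mask & any_nb_bg,     # tumor voxels touching background
       outer = !mask & any_nb_fg)    # background voxels touching tumor
}

# One repeated segmentation: independent boundary flips plus a partial
# one-voxel dilation or erosion (a biased extra flip pass on one shell).
perturb_mask <- function(mask, jitter) {
  if (jitter <= 0) return(mask)
  sh <- mask_shells(mask)
  out <- mask
  inner_idx <- which(sh$inner)
  outer_idx <- which(sh$outer)
  flip_in <- inner_idx[runif(length(inner_idx)) < jitter]
  flip_out <- outer_idx[runif(length(outer_idx)) < jitter]
  out[flip_in] <- FALSE
  out[flip_out] <- TRUE
  if (runif(1) < 0.5) {  # partial dilation
    extra <- outer_idx[runif(length(outer_idx)) < jitter]
    out[extra] <- TRUE
  } else {               # partial erosion
    extra <- inner_idx[runif(length(inner_idx)) < jitter]
    out[extra] <- FALSE
  }
  if (!any(out)) out <- mask
  out
}

#' Generate a synthetic imaging cohort
#'
#' Draws one ellipsoidal lesion per patient (per-axis radii from the
#' class-specific range), fills the four sequences with class-dependent
#' textured intensities (Gaussian random field with class correlation
#' length on top of a per-sequence mean), and produces
#' `n_readers * n_sessions` segmentations per patient by perturbing the
#' true mask's boundary.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`, `label`
#'   (factor GBM/MET), `volumes` (named list of 4 [image_volume()]),
#'   `masks` (named list of `roi_mask`, names `r<reader>s<session>`), and
#'   `mask_true` (the unperturbed lesion).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4,
#'   volume_shape = c(16, 16, 16), seed = 7))
#' cohort$label
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    n_gbm <- round(n * config$class_balance)
    labels <- factor(c(rep("GBM", n_gbm), rep("MET", n - n_gbm)),
                     levels = c("GBM", "MET"))
    shape <- config$volume_shape
    sp <- config$voxel_spacing
    seqs <- mri_sequences()
    occ <- as.vector(outer(seq_len(config$n_sessions),
                           seq_len(config$n_readers),
                           function(s, r) sprintf("r%ds%d", r, s)))
    rows <- purrr::map(seq_len(n), function(i) {
      cls <- as.character(labels[i])
      tex <- config$texture[[cls]]
      rr <- config$tumor_radius_range[[cls]]
      radii <- runif(3, rr[1], rr[2])
      center <- (shape * sp) / 2 + runif(3, -1, 1)
      ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) * sp[a]))
      g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
      inside <- ((g$x - center[1]) / radii[1])^2 +
        ((g$y - center[2]) / radii[2])^2 +
        ((g$z - center[3]) / radii[3])^2 <= 1
      mask_true <- array(inside, shape)
      vols <- purrr::map(seq_along(seqs), function(k) {
        field <- gaussian_random_field(shape, sp, tex$corr_len)
        vox <- 40 + 8 * array(rnorm(prod(shape)), shape)   # background tissue
        vox[mask_true] <- tex$mean[k] + tex$sd * field[mask_true]
        image_volume(vox, spacing = sp)
      })
      names(vols) <- seqs
      masks <- purrr::map(occ, function(o) {
        roi_mask(perturb_mask(mask_true, config$reader_jitter), spacing = sp)
      })
      names(masks) <- occ
      list(volumes = vols, masks = masks,
           mask_true = roi_mask(mask_true, spacing = sp))
    })
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      label = labels,
      volumes = purrr::map(rows, "volumes"),
      masks = purrr::map(rows, "masks"),
      mask_true = purrr::map(rows, "mask_true")
    )
  })
}

#' Configuration for a synthetic feature table
#'
#' Generates a patients x features table directly (skipping image synthesis
#' and extraction) with a planted class signal: `n_informative` columns get
#' a class-conditional mean difference of `effect_size` (in units of
#' `noise_sd`, which defaults to 1) before i.i.d. Gaussian noise is added.
#'
#' @param n_patients Number of rows.
#' @param n_features_per_sequence Features per sequence (default 107, the
#'   full extraction panel).
#' @param n_sequences Number of sequences (default 4).
#' @param n_informative Number of columns carrying the class signal.
#' @param effect_size Standardized between-class mean shift (>= 0).
#' @param noise_sd Noise standard deviation (> 0).
#' @param class_balance Fraction of class GBM.
#' @param seed Integer seed.
#' @return A `feature_table_config` list.
#' @export
feature_table_config <- function(n_patients = 91,
                                 n_features_per_sequence = 107,
                                 n_sequences = 4,
                                 n_informative = 20,
                                 effect_size = 1,
                                 noise_sd = 1,
                                 class_balance = 51 / 91,
                                 seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be positive.")
  }
  total <- n_features_per_sequence * n_sequences
  if (n_informative > total) {
    abort("`n_informative` cannot exceed the total number of feature columns.")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  structure(
    list(n_patients = as.integer(n_patients),
         n_features_per_sequence = as.integer(n_features_per_sequence),
         n_sequences = as.integer(n_sequences),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         class_balance = class_balance, seed = as.integer(seed)),
    class = "feature_table_config"
  )
}

synthetic_feature_names <- function(n_per_seq, n_seq) {
  seqs <- mri_sequences()[seq_len(n_seq)]
  base <- if (n_per_seq == 107L) {
    feature_names_107()
  } else {
    fams <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
    sprintf("%s_x%03d", fams[(seq_len(n_per_seq) - 1) %% length(fams) + 1],
            seq_len(n_per_seq))
  }
  as.vector(t(outer(seqs, base, paste, sep = "_")))
}

#' Generate a synthetic feature table with planted class structure
#'
#' @param config A [feature_table_config()].
#' @return A tibble with `patient_id`, `label`, and
#'   `n_features_per_sequence * n_sequences` numeric feature columns whose
#'   names encode sequence and feature family. The planted informative
#'   columns are recorded in the `"informative"` attribute.
#' @export
#' @examples
#' tbl <- generate_feature_table(feature_table_config(n_patients = 12, seed = 3))
#' ncol(tbl) - 2L   # 428 feature columns
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "feature_table_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    p <- config$n_features_per_sequence * config$n_sequences
    nms <- synthetic_feature_names(config$n_features_per_sequence,
                                   config$n_sequences)
    n_gbm <- round(n * config$class_balance)
    labels <- factor(c(rep("GBM", n_gbm), rep("MET", n - n_gbm)),
                     levels = c("GBM", "MET"))
    info <- sort(sample.int(p, config$n_informative))
    mu <- matrix(0, n, p)
    shift <- config$effect_size * config$noise_sd
    mu[labels == "GBM", info] <- shift / 2
    mu[labels == "MET", info] <- -shift / 2
    X <- mu + matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    colnames(X) <- nms
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%03d", seq_len(n)), label = labels),
      tibble::as_tibble(X)
    )
    attr(out, "informative") <- nms[info]
    out
  })
}

#' Read / write feature tables as CSV
#'
#' The CSV has one header row of feature names plus `patient_id` and
#' `label` columns; `label` round-trips as a GBM/MET factor.
#'
#' @param tbl A feature table tibble.
#' @param path CSV path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tbl)) {
    tbl$label <- factor(tbl$label, levels = c("GBM", "MET"))
  }
  tibble::as_tibble(tbl)
}

#' Dice overlap between two masks
#'
#' @param a,b `roi_mask` objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  av <- a$voxels; bv <- b$voxels
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
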